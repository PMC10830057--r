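id,sex,age,total_cholesterol,hdl,ldl,triglycerides,fasting_glucose,bmi,sbp,bp_treated,smoker,diabetes,prior_cvd,event,event_code,followup_years
k1,male,45,210,48,130,150,95,24.5,128,0,1,0,0,0,,10
k2,female,52,198,62,115,98,88,22.1,118,1,0,0,0,1,I63,6.25
k3,male,61,240,41,160,210,130,27.9,145,0,1,1,0,1,I21.4,2.5
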