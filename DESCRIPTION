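Package: riskbench
Title: Benchmarking 10-Year Cardiovascular Risk Equations on Synthetic Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to evaluate sex-specific 10-year cardiovascular disease
    risk equations (the general-CVD Framingham risk score and the pooled
    cohort ASCVD equations) on tabular cohorts: cohort validation with
    eligibility, exclusion and outlier filters; ICD-10 composite outcome
    mapping and person-year incidence rates with exact Poisson intervals;
    risk-engine scoring from auditable coefficient tables, including
    cross-sex coefficient transfer; discrimination (AUC with DeLong
    variance and the paired DeLong test) and calibration (decile
    Hosmer-Lemeshow) statistics; an exhaustive cross-validated Cox
    covariate-subset search; a leave-one-term-out variance-importance
    statistic; and a Gaussian-copula synthetic cohort generator calibrated
    to published Korean claims-cohort summary statistics, so the whole
    pipeline is testable without access to restricted claims data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    pROC,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
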