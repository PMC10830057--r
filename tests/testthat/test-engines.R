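test_that("packaged coefficient tables carry the published term structure", {
  fm <- builtin_spec("framingham", "male")
  expect_setequal(
    names(fm$terms),
    c("ln_age", "ln_total_cholesterol", "ln_hdl", "ln_sbp_treated",
      "ln_sbp_untreated", "smoker", "diabetes")
  )
  af <- builtin_spec("ascvd", "female")
  expect_true("ln_age_square" %in% names(af$terms))
  am <- builtin_spec("ascvd", "male")
  expect_true(all(c(
    "ln_age_x_ln_total_cholesterol", "ln_age_x_ln_hdl", "ln_age_x_smoker"
  ) %in% names(am$terms)))
  expect_false("ln_age_square" %in% names(am$terms))
  expect_error(builtin_spec("framingham", "other"))
})

reference_profile <- function(sex = "male") {
  base_record("ref", sex = sex, age = 55, total_cholesterol = 213, hdl = 50,
              sbp = 120, bp_treated = 0L, smoker = 0L, diabetes = 0L)
}

test_that("scoring matches independent term-by-term arithmetic on a reference profile", {
  prof <- reference_profile()
  fm <- builtin_spec("framingham", "male")
  l_oracle <- 3.06117 * log(55) + 1.12370 * log(213) - 0.93263 * log(50) +
    1.93303 * log(120) - 23.9802
  expect_equal(linear_predictor(prof, fm), l_oracle, tolerance = 1e-12)
  expect_equal(predict_risk(prof, fm)$risk, 1 - 0.88936^exp(l_oracle),
               tolerance = 1e-12)

  am <- builtin_spec("ascvd", "male")
  l_am <- 12.344 * log(55) + 11.853 * log(213) - 2.664 * log(55) * log(213) -
    7.990 * log(50) + 1.769 * log(55) * log(50) + 1.764 * log(120) - 61.18
  expect_equal(linear_predictor(prof, am), l_am, tolerance = 1e-12)
  # published worked example for this non-smoking, non-diabetic profile:
  # 5.3% (men) / 2.1% (women) 10-year risk, printed to one decimal
  expect_equal(100 * predict_risk(prof, am)$risk, 5.3, tolerance = 0.1)
  af <- builtin_spec("ascvd", "female")
  expect_equal(100 * predict_risk(prof, af)$risk, 2.1, tolerance = 0.1)
})

test_that("mean-centering makes L = 0 and risk = 1 - S0 at the mean profile", {
  prof <- reference_profile()
  fm <- builtin_spec("framingham", "male")
  raw <- linear_predictor(prof, fm) + fm$mean_lp
  centered <- risk_engine_spec("custom", "male", fm$terms, mean_lp = raw,
                               baseline_survival = fm$baseline_survival)
  expect_equal(linear_predictor(prof, centered), 0, tolerance = 1e-12)
  expect_equal(predict_risk(prof, centered)$risk, 1 - fm$baseline_survival,
               tolerance = 1e-12)
})

test_that("risk is monotone in SBP and age and exactly one SBP term fires", {
  fm <- builtin_spec("framingham", "male")
  grid <- dplyr::bind_rows(lapply(seq(100, 180, by = 5), function(s) {
    base_record(sprintf("s%d", s), sbp = s)
  }))
  risks <- predict_risk(grid, fm)$risk
  expect_true(all(diff(risks) > 0))
  ages <- dplyr::bind_rows(lapply(seq(35, 70, by = 5), function(a) {
    base_record(sprintf("a%d", a), age = a)
  }))
  expect_true(all(diff(predict_risk(ages, fm)$risk) > 0))
  # treated vs untreated SBP: flipping the flag swaps which coefficient applies
  rec <- base_record("t", sbp = 140, bp_treated = 1L)
  rec0 <- base_record("u", sbp = 140, bp_treated = 0L)
  contrib1 <- riskbench:::term_matrix(rec, fm$terms)
  contrib0 <- riskbench:::term_matrix(rec0, fm$terms)
  expect_equal(unname(contrib1[, "ln_sbp_untreated"]), 0)
  expect_equal(unname(contrib0[, "ln_sbp_treated"]), 0)
  expect_gt(contrib1[, "ln_sbp_treated"], 0)
})

test_that("risk stays inside [0,1] and scoring is pure", {
  am <- builtin_spec("ascvd", "female")
  cov <- generate_covariates(500, sex = "female", seed = 3)
  r1 <- predict_risk(cov, am)
  r2 <- predict_risk(cov, am)
  expect_identical(r1, r2)
  expect_true(all(r1$risk >= 0 & r1$risk <= 1))
})

test_that("coefficient transfer relabels without changing any numbers", {
  fm <- builtin_spec("framingham", "male")
  tr <- transfer_spec(fm, "female")
  expect_equal(tr$sex, "female")
  female_rec <- reference_profile(sex = "female")
  male_rec <- reference_profile(sex = "male")
  expect_equal(predict_risk(female_rec, tr)$risk,
               predict_risk(male_rec, fm)$risk)
  expect_equal(transfer_spec(fm, "male"), fm)
})

test_that("engine specs round-trip through their coefficient-table files", {
  for (engine in c("framingham", "ascvd")) {
    sp <- builtin_spec(engine, "female")
    path <- withr::local_tempfile(fileext = ".csv")
    write_engine_spec(sp, path)
    back <- read_engine_spec(path, engine = engine, sex = "female")
    expect_identical(tidy(back), tidy(sp))
    expect_identical(back$mean_lp, sp$mean_lp)
    expect_identical(back$baseline_survival, sp$baseline_survival)
  }
})

test_that("log transforms reject non-positive covariates by name", {
  rec <- base_record("bad", hdl = 0)
  expect_error(
    linear_predictor(rec, builtin_spec("framingham", "male")),
    "hdl"
  )
})

test_that("a spec with all-zero coefficients and offset scores L = 0", {
  terms <- list(risk_term("ln_age", "age", "ln", 0),
                risk_term("smoker", "smoker", "identity", 0))
  sp <- risk_engine_spec("custom", "male", terms, mean_lp = 0,
                         baseline_survival = 0.9)
  expect_equal(linear_predictor(base_record("x"), sp), 0)
  expect_equal(predict_risk(base_record("x"), sp)$risk, 1 - 0.9)
})
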