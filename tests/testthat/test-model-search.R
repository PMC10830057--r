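test_that("the Cox fit matches a hand-written partial-likelihood oracle on toy data", {
  # four records, two events, one binary covariate; Breslow partial
  # likelihood written out and maximized numerically as the oracle
  coh <- dplyr::bind_rows(
    base_record("a", smoker = 1L, event = 1L, event_code = "I63", followup_years = 1),
    base_record("b", smoker = 0L, event = 1L, event_code = "I21", followup_years = 2),
    base_record("c", smoker = 1L),
    base_record("d", smoker = 0L)
  )
  x <- c(1, 0, 1, 0)
  neg_log_pl <- function(beta) {
    risk <- exp(beta * x)
    -(beta * x[1] - log(sum(risk)) + beta * x[2] - log(sum(risk[2:4])))
  }
  oracle <- optimize(neg_log_pl, c(-5, 5))$minimum
  fit <- fit_cox(coh, list(risk_term("smoker", "smoker", "identity", 0)))
  expect_equal(unname(fit$coefficients), oracle, tolerance = 1e-4)
  expect_equal(fit$log_partial_likelihood, -neg_log_pl(fit$coefficients[[1]]),
               tolerance = 1e-8)
  expect_equal(fit$convergence, "converged")
})

test_that("a constant covariate carries no information", {
  coh <- known_cox_cohort(300, seed = 5)
  fit <- fit_cox(coh, list(risk_term("diabetes", "diabetes", "identity", 0)))
  expect_equal(unname(fit$coefficients), 0)
  expect_equal(fit$log_partial_likelihood, fit$null_log_partial_likelihood)
})

test_that("fitting requires at least one event", {
  expect_error(
    fit_cox(base_cohort(5), list(risk_term("smoker", "smoker", "identity", 0))),
    "no events"
  )
})

test_that("known coefficients are recovered within 3 standard errors", {
  coh <- known_cox_cohort(20000, beta = 2, beta_bin = 0.7, seed = 17)
  fit <- fit_cox(coh, list(
    risk_term("ln_sbp", "sbp", "ln", 0),
    risk_term("smoker", "smoker", "identity", 0)
  ))
  est <- tidy(fit)
  expect_true(abs(est$estimate[1] - 2) <= 3 * est$std.error[1])
  expect_true(abs(est$estimate[2] - 0.7) <= 3 * est$std.error[2])
  # the fit round-trips into a scoring spec whose risks are monotone in lp
  spec <- as_engine_spec(fit)
  pred <- predict_risk(coh[1:50, ], spec)
  expect_equal(order(pred$risk), order(pred$linear_predictor))
})

test_that("subset enumeration covers every non-empty subset exactly once", {
  coh <- known_cox_cohort(800, seed = 23)
  pool <- list(
    ln_sbp = risk_term("ln_sbp", "sbp", "ln", 0),
    smoker = risk_term("smoker", "smoker", "identity", 0),
    ln_bmi = risk_term("ln_bmi", "bmi", "ln", 0)
  )
  res <- cv_subset_search(coh, pool, folds = 3, seed = 1)
  expect_equal(res$n_subsets, 7)
  expect_equal(nrow(res$subsets), 7)
  expect_equal(anyDuplicated(res$subsets$subset), 0)
  expect_length(res$per_fold_auc, 3)
  expect_true(all(res$subsets$cv_auc >= 0 & res$subsets$cv_auc <= 1))
})

test_that("a single-entry pool returns that entry", {
  coh <- known_cox_cohort(400, seed = 29)
  res <- cv_subset_search(
    coh, list(ln_sbp = risk_term("ln_sbp", "sbp", "ln", 0)),
    folds = 3, seed = 1
  )
  expect_equal(res$best_subset, "ln_sbp")
  expect_equal(res$n_subsets, 1)
})

test_that("stratified folds partition the cohort with events in every fold", {
  ev <- c(rep(TRUE, 20), rep(FALSE, 180))
  fold <- riskbench:::assign_folds(ev, 5, seed = 3)
  expect_equal(sort(unique(fold)), 1:5)
  expect_equal(length(fold), 200)
  expect_true(all(tapply(ev, fold, sum) == 4))   # 20 events split 4/fold
  expect_true(all(table(fold) == 40))
})

test_that("the search keeps the signal covariate and mostly drops pure noise", {
  # outcomes driven by ln(sbp) only; fasting glucose is independent noise
  winners <- lapply(1:4, function(seed) {
    coh <- known_cox_cohort(2500, beta = 3, beta_bin = 0, lambda0 = 4e-9,
                            seed = 100 + seed)
    coh$fasting_glucose <- withr::with_seed(200 + seed,
                                            exp(rnorm(2500, log(92), 0.2)))
    pool <- list(
      ln_sbp = risk_term("ln_sbp", "sbp", "ln", 0),
      noise = risk_term("ln_glucose", "fasting_glucose", "ln", 0)
    )
    cv_subset_search(coh, pool, folds = 5, seed = seed)$best_subset
  })
  expect_true(all(vapply(winners, function(w) "ln_sbp" %in% w, logical(1))))
  noise_runs <- sum(vapply(winners, function(w) "noise" %in% w, logical(1)))
  expect_lt(noise_runs / length(winners), 0.5)
})

test_that("variance importance matches the closed form for independent covariates", {
  n <- 5000
  coh <- withr::with_seed(31, dplyr::mutate(
    base_cohort(n),
    age = rnorm(n, 50, 5),
    sbp = rnorm(n, 125, 10)
  ))
  terms <- list(
    risk_term("age", "age", "identity", 0.4),
    risk_term("sbp", "sbp", "identity", -0.2)
  )
  sp <- risk_engine_spec("custom", "male", terms, mean_lp = 0,
                         baseline_survival = 0.9)
  imp <- variance_importance(sp, coh)
  expected <- 100 * c(0.4^2 * 25, 0.2^2 * 100) / (0.4^2 * 25 + 0.2^2 * 100)
  expect_equal(imp$variance_share, expected, tolerance = 0.05)
  # shifting a covariate by a constant leaves variance shares unchanged
  shifted <- dplyr::mutate(coh, age = age + 10)
  expect_equal(variance_importance(sp, shifted)$variance_share,
               imp$variance_share, tolerance = 1e-10)
})

test_that("degenerate and boundary importance cases follow the definition", {
  coh <- known_cox_cohort(200, seed = 37)
  single <- risk_engine_spec(
    "custom", "male", list(risk_term("ln_sbp", "sbp", "ln", 1.5)),
    mean_lp = 0, baseline_survival = 0.9
  )
  expect_equal(variance_importance(single, coh)$variance_share, 100)
  with_zero <- risk_engine_spec(
    "custom", "male",
    list(risk_term("ln_sbp", "sbp", "ln", 1.5),
         risk_term("smoker", "smoker", "identity", 0)),
    mean_lp = 0, baseline_survival = 0.9
  )
  imp <- variance_importance(with_zero, coh)
  expect_equal(imp$variance_share[imp$term == "smoker"], 0)
  constant <- risk_engine_spec(
    "custom", "male", list(risk_term("diabetes", "diabetes", "identity", 1)),
    mean_lp = 0, baseline_survival = 0.9
  )
  expect_error(variance_importance(constant, coh), "zero variance")
})

test_that("engine importance tables separate the treated/untreated SBP rows", {
  cov <- generate_covariates(2000, sex = "male", seed = 41)
  imp <- variance_importance(builtin_spec("framingham", "male"), cov)
  expect_true(all(c("ln_sbp_treated", "ln_sbp_untreated") %in% imp$term))
  expect_equal(nrow(imp), 7)
})
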