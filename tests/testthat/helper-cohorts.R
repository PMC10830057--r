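# Builders for small deterministic cohorts used across the suite.

# A valid participant row; override any field through ...
base_record <- function(id = "p1", ...) {
  rec <- tibble::tibble(
    id = id, sex = "male", age = 50, total_cholesterol = 200, hdl = 50,
    ldl = 120, triglycerides = 130, fasting_glucose = 90, bmi = 24,
    sbp = 125, bp_treated = 0L, smoker = 0L, diabetes = 0L, prior_cvd = 0L,
    event = 0L, event_code = "", followup_years = 10
  )
  dots <- list(...)
  for (nm in names(dots)) rec[[nm]] <- dots[[nm]]
  rec
}

# n copies of the base record with distinct ids (vectorized).
base_cohort <- function(n, ...) {
  rec <- base_record(...)
  coh <- rec[rep(1L, n), ]
  coh$id <- sprintf("p%05d", seq_len(n))
  coh
}

# 10-record toy cohort with one under-age, one prior-CVD and one
# total-cholesterol outlier planted (rows 1-3).
toy_exclusion_cohort <- function() {
  dplyr::bind_rows(
    base_record("u1", age = 25),
    base_record("c1", prior_cvd = 1L),
    base_record("t1", total_cholesterol = 350),
    base_cohort(7)
  )
}

# Simulated survival cohort from a known Cox model over ln(sbp) (log-hazard
# slope `beta`) plus a binary smoker effect `beta_bin`, exponential baseline.
known_cox_cohort <- function(n, beta = 2, beta_bin = 0.7, lambda0 = 5e-6,
                             seed = 1) {
  withr::with_seed(seed, {
    sbp <- exp(rnorm(n, log(125), 0.12))
    smoker <- rbinom(n, 1, 0.4)
    rate <- lambda0 * exp(beta * log(sbp) + beta_bin * smoker)
    t <- rexp(n, rate)
    evt <- t <= 10
    coh <- base_cohort(n)
    coh$sbp <- sbp
    coh$smoker <- as.integer(smoker)
    coh$event <- as.integer(evt)
    coh$event_code <- ifelse(evt, "I63", "")
    coh$followup_years <- ifelse(evt, pmax(t, 1e-6), 10)
    coh
  })
}

# Brute-force AUC by exhaustive positive-negative pair counting (+1/2 per
# tie); the independent oracle for roc_auc on small vectors.
pair_count_auc <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  mean(outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q)))
}
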