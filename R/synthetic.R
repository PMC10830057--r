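# Synthetic cohort generation: Gaussian-copula covariates calibrated to
# published sex-specific summary statistics, and 10-year outcomes from
# either a "true" risk engine or subtype-specific constant hazards.

.continuous_spec_cols <- c(
  "age", "bmi", "fasting_glucose", "total_cholesterol", "ldl", "hdl",
  "triglycerides", "sbp"
)
.binary_spec_cols <- c("smoker", "diabetes", "bp_treated")

# Published cohort summary statistics by sex (means/SDs and prevalences).
# bp_treated uses the reported hypertension prevalence as a stand-in: the
# source reports hypertension, not treatment, prevalence.
.table1 <- list(
  male = list(
    mean = c(age = 42.5, bmi = 23.7, fasting_glucose = 92.4,
             total_cholesterol = 193.1, ldl = 115.2, hdl = 51.9,
             triglycerides = 149.0, sbp = 123.4),
    sd = c(age = 10.1, bmi = 2.8, fasting_glucose = 19.4,
           total_cholesterol = 32.3, ldl = 35.8, hdl = 12.3,
           triglycerides = 97.0, sbp = 14.9),
    prevalence = c(smoker = 0.448, diabetes = 0.038, bp_treated = 0.062)
  ),
  female = list(
    mean = c(age = 46.3, bmi = 22.9, fasting_glucose = 89.9,
             total_cholesterol = 191.5, ldl = 119.2, hdl = 58.0,
             triglycerides = 107.7, sbp = 117.8),
    sd = c(age = 9.9, bmi = 2.9, fasting_glucose = 17.2,
           total_cholesterol = 34.0, ldl = 34.7, hdl = 13.0,
           triglycerides = 64.4, sbp = 16.6),
    prevalence = c(smoker = 0.019, diabetes = 0.030, bp_treated = 0.071)
  )
)

#' Default latent correlation matrix for the covariate generator
#'
#' The source tables publish only marginals, so these modest correlations
#' are invented, documented, and overridable: positive links among
#' adiposity, blood pressure, glucose and triglycerides; a strong
#' total-LDL cholesterol correlation; a negative HDL-triglyceride link;
#' diabetes and treated-hypertension latents tied to glucose and SBP.
#'
#' @return An 11 x 11 symmetric positive-definite correlation matrix over
#'   the latent normal drivers (8 continuous covariates + 3 binary flags).
#' @export
default_correlation <- function() {
  vars <- c(.continuous_spec_cols, .binary_spec_cols)
  r <- diag(length(vars))
  dimnames(r) <- list(vars, vars)
  set_r <- function(a, b, value) {
    r[a, b] <<- value
    r[b, a] <<- value
  }
  set_r("age", "sbp", 0.30)
  set_r("age", "fasting_glucose", 0.15)
  set_r("age", "total_cholesterol", 0.15)
  set_r("age", "bmi", 0.10)
  set_r("age", "bp_treated", 0.20)
  set_r("bmi", "sbp", 0.25)
  set_r("bmi", "triglycerides", 0.30)
  set_r("bmi", "fasting_glucose", 0.20)
  set_r("bmi", "hdl", -0.25)
  set_r("fasting_glucose", "triglycerides", 0.20)
  set_r("fasting_glucose", "diabetes", 0.60)
  set_r("total_cholesterol", "ldl", 0.85)
  set_r("total_cholesterol", "hdl", 0.15)
  set_r("total_cholesterol", "triglycerides", 0.30)
  set_r("ldl", "triglycerides", 0.25)
  set_r("ldl", "hdl", -0.05)
  set_r("hdl", "triglycerides", -0.40)
  set_r("sbp", "bp_treated", 0.55)
  r
}

#' Covariate-generator specification
#'
#' Packaged defaults (`covariate_spec("male")`, `covariate_spec("female")`)
#' transcribe the published sex-specific means, SDs and prevalences; the
#' latent correlation defaults to [default_correlation()].
#'
#' @param sex `"male"` or `"female"` (selects the packaged marginals).
#' @param mean,sd Named numeric vectors over the continuous covariates
#'   (age, bmi, fasting_glucose, total_cholesterol, ldl, hdl,
#'   triglycerides, sbp); defaults from the packaged table.
#' @param prevalence Named vector over smoker, diabetes, bp_treated.
#' @param correlation Latent correlation matrix (continuous covariates
#'   then binary flags); must be symmetric positive definite with unit
#'   diagonal.
#' @param positive_floor Continuous draws are floored at this value so all
#'   records satisfy the strict-positivity invariant; the untruncated
#'   normal marginals otherwise keep sample moments unbiased.
#' @return A `covariate_spec` object.
#' @export
covariate_spec <- function(sex = c("male", "female"), mean = NULL, sd = NULL,
                           prevalence = NULL, correlation = default_correlation(),
                           positive_floor = 1) {
  sex <- match.arg(sex)
  defaults <- .table1[[sex]]
  mean <- c(mean, defaults$mean[setdiff(names(defaults$mean), names(mean))])[.continuous_spec_cols]
  sd <- c(sd, defaults$sd[setdiff(names(defaults$sd), names(sd))])[.continuous_spec_cols]
  prevalence <- c(prevalence, defaults$prevalence[setdiff(names(defaults$prevalence), names(prevalence))])[.binary_spec_cols]
  if (any(sd <= 0)) abort("all SDs must be strictly positive")
  if (any(prevalence < 0 | prevalence > 1)) abort("prevalences must lie in [0, 1]")
  vars <- c(.continuous_spec_cols, .binary_spec_cols)
  if (!identical(dim(correlation), c(length(vars), length(vars)))) {
    abort("`correlation` must be 11 x 11 (continuous covariates then flags)")
  }
  if (!isTRUE(all.equal(correlation, t(correlation))) ||
      !isTRUE(all.equal(unname(diag(correlation)), rep(1, length(vars))))) {
    abort("`correlation` must be symmetric with unit diagonal")
  }
  chol_ok <- tryCatch({ chol(correlation); TRUE }, error = function(e) FALSE)
  if (!chol_ok) abort("`correlation` must be positive definite")
  structure(
    list(
      sex = sex, mean = mean, sd = sd, prevalence = prevalence,
      correlation = correlation, positive_floor = positive_floor
    ),
    class = "covariate_spec"
  )
}

#' Draw a synthetic covariate cohort (no outcomes)
#'
#' Latent standard normals with the spec's correlation are mapped to the
#' continuous covariates by affine transform (untruncated, so sample
#' moments are unbiased, then floored at `positive_floor`) and to the
#' binary flags by thresholding at the prevalence quantile. Deterministic
#' given the seed.
#'
#' @param n Number of participants.
#' @param spec A [covariate_spec()]; default the packaged spec for `sex`.
#' @param sex Used when `spec` is NULL to pick the packaged defaults.
#' @param seed Integer seed.
#' @return A tibble with the cohort covariate columns (outcome columns
#'   absent; `prior_cvd` all FALSE).
#' @export
generate_covariates <- function(n, spec = NULL, sex = c("male", "female"),
                                seed = 1L) {
  sex <- match.arg(sex)
  if (is.null(spec)) spec <- covariate_spec(sex)
  stopifnot(inherits(spec, "covariate_spec"), n >= 1)
  vars <- c(.continuous_spec_cols, .binary_spec_cols)
  z <- withr::with_seed(seed, {
    matrix(rnorm(n * length(vars)), nrow = n) %*% chol(spec$correlation)
  })
  colnames(z) <- vars
  out <- tibble::tibble(
    id = sprintf("%s-%07d", substr(spec$sex, 1, 1), seq_len(n)),
    sex = spec$sex
  )
  for (v in .continuous_spec_cols) {
    out[[v]] <- pmax(spec$mean[[v]] + spec$sd[[v]] * z[, v], spec$positive_floor)
  }
  for (v in .binary_spec_cols) {
    out[[v]] <- as.integer(z[, v] > qnorm(1 - spec$prevalence[[v]]))
  }
  out$prior_cvd <- 0L
  # cohort column order (outcomes absent)
  out[, c("id", "sex", "age", "total_cholesterol", "hdl", "ldl",
          "triglycerides", "fasting_glucose", "bmi", "sbp", "bp_treated",
          "smoker", "diabetes", "prior_cvd")]
}

# Published per-subtype incidence rates (events per 100,000 person-years).
# With constant competing hazards and 10-year administrative censoring the
# empirical events/person-years rate is an unbiased estimator of the
# per-subtype hazard, so the hazards are the printed rates rescaled.
.table2_rates <- list(
  male = c(
    I63 = 240.65, I61 = 24.73, G45 = 28.09, I50 = 14.63, I48 = 107.44,
    I20 = 117.42, I21 = 89.38, I60 = 12.26, I46 = 11.07, I62 = 9.88
  ),
  female = c(
    I63 = 327.63, I61 = 23.94, G45 = 52.11, I50 = 23.93, I48 = 90.38,
    I20 = 118.73, I21 = 81.36, I60 = 20.04, I46 = 4.78, I62 = 4.78
  )
)

#' Packaged per-subtype hazards calibrated to published incidence rates
#'
#' @param sex `"male"` or `"female"`.
#' @return Named vector of constant hazards (events per person-year) per
#'   ICD-10 subtype category.
#' @export
subtype_hazards <- function(sex = c("male", "female")) {
  sex <- match.arg(sex)
  .table2_rates[[sex]] / 1e5
}

#' Outcome-simulation specification
#'
#' Two modes: `"engine_true_risk"` treats a risk-engine spec as the true
#' 10-year risk model (event drawn Bernoulli at the engine risk, event
#' time uniform on (0, 10], subtype code drawn from the sex-specific
#' published event mix); `"subtype_hazards"` draws competing exponential
#' event times with constant per-subtype hazards, the first arrival before
#' 10 years becoming the event.
#'
#' @param mode `"engine_true_risk"` or `"subtype_hazards"`.
#' @param engine A `risk_engine_spec` (engine mode).
#' @param hazards Named per-subtype hazards per person-year (hazard mode);
#'   defaults to [subtype_hazards()] for the scored sex.
#' @param horizon Follow-up horizon in years, default 10.
#' @return An `outcome_spec` object.
#' @export
outcome_spec <- function(mode = c("engine_true_risk", "subtype_hazards"),
                         engine = NULL, hazards = NULL, horizon = 10) {
  mode <- match.arg(mode)
  if (mode == "engine_true_risk" && !inherits(engine, "risk_engine_spec")) {
    abort("engine mode needs a `risk_engine_spec` as ground truth")
  }
  if (!is.null(hazards) && any(hazards < 0)) abort("hazards must be non-negative")
  if (horizon <= 0) abort("`horizon` must be positive")
  structure(
    list(mode = mode, engine = engine, hazards = hazards, horizon = horizon),
    class = "outcome_spec"
  )
}

#' Simulate 10-year outcomes onto a covariate cohort
#'
#' @param cohort A covariate tibble from [generate_covariates()] (no
#'   outcome columns yet).
#' @param spec An [outcome_spec()].
#' @param seed Integer seed.
#' @return The cohort completed with `event`, `event_code`,
#'   `followup_years`; validates as a full cohort.
#' @export
simulate_outcomes <- function(cohort, spec, seed = 1L) {
  stopifnot(inherits(spec, "outcome_spec"))
  if ("event" %in% names(cohort)) abort("cohort already carries outcomes")
  n <- nrow(cohort)
  sex <- unique(cohort$sex)[1]
  horizon <- spec$horizon
  res <- withr::with_seed(seed, {
    if (spec$mode == "engine_true_risk") {
      risk <- predict_risk(cohort, spec$engine)$risk
      event <- rbinom(n, 1, risk) == 1
      time <- ifelse(event, runif(n, 0, horizon), horizon)
      mix <- .table2_rates[[sex]]
      code <- rep(NA_character_, n)
      code[event] <- sample(names(mix), sum(event), replace = TRUE,
                            prob = mix / sum(mix))
      list(event = event, code = code, time = pmax(time, 1e-9))
    } else {
      hz <- spec$hazards
      if (is.null(hz)) hz <- subtype_hazards(sex)
      total <- sum(hz)
      if (total == 0) {
        list(event = rep(FALSE, n), code = rep(NA_character_, n),
             time = rep(horizon, n))
      } else {
        t_first <- rexp(n, rate = total)
        event <- t_first <= horizon
        code <- rep(NA_character_, n)
        code[event] <- sample(names(hz), sum(event), replace = TRUE,
                              prob = hz / total)
        list(event = event, code = code,
             time = ifelse(event, pmax(t_first, 1e-9), horizon))
      }
    }
  })
  out <- cohort
  out$event <- as.integer(res$event)
  out$event_code <- ifelse(res$event, res$code, "")
  out$followup_years <- res$time
  validate_cohort(out)
  out
}

#' Generate a pre-filter cohort with planted exclusions
#'
#' Emits a raw cohort in which specified fractions of records
#' deterministically violate each exclusion rule (disjoint blocks, exact
#' counts: `floor(n * fraction)` records per rule), so the filter
#' cascade's counts are known by construction.
#'
#' @param n Cohort size before filtering.
#' @param planted Named fractions over `under_age`, `prior_cvd`,
#'   `tc_outlier`, `hdl_outlier`, `bmi_outlier`, `ldl_outlier`,
#'   `tg_outlier`; must sum to at most 1.
#' @param sex,seed As in [generate_covariates()].
#' @return A full cohort tibble (hazard-mode outcomes attached).
#' @export
generate_raw_cohort <- function(n, planted = c(under_age = 0.1),
                                sex = c("male", "female"), seed = 1L) {
  sex <- match.arg(sex)
  allowed <- c("under_age", "prior_cvd", "tc_outlier", "hdl_outlier",
               "bmi_outlier", "ldl_outlier", "tg_outlier")
  if (length(planted) > 0) {
    if (is.null(names(planted)) || !all(names(planted) %in% allowed)) {
      abort(paste0("`planted` names must be among: ", paste(allowed, collapse = ", ")))
    }
    if (any(planted < 0) || sum(planted) > 1) {
      abort("`planted` fractions must be non-negative and sum to at most 1")
    }
  }
  cov <- generate_covariates(n, sex = sex, seed = seed)
  # keep base records clear of all exclusion margins so planted counts are exact
  cov$age <- pmin(pmax(cov$age, 30), 90)
  cov$total_cholesterol <- pmin(cov$total_cholesterol, 300)
  cov$hdl <- pmin(cov$hdl, 100)
  cov$bmi <- pmin(cov$bmi, 100)
  cov$ldl <- pmin(cov$ldl, 1000)
  cov$triglycerides <- pmin(cov$triglycerides, 1500)
  counts <- vapply(planted, function(f) as.integer(floor(n * f)), integer(1))
  start <- 1L
  plant_rows <- function(k) {
    rows <- seq_len(k) + start - 1L
    start <<- start + k
    rows
  }
  u <- withr::with_seed(seed + 1L, runif(n))
  for (rule in names(counts)) {
    rows <- plant_rows(counts[[rule]])
    if (length(rows) == 0) next
    switch(rule,
      under_age = { cov$age[rows] <- 20 + 9 * u[rows] },
      prior_cvd = { cov$prior_cvd[rows] <- 1L },
      tc_outlier = { cov$total_cholesterol[rows] <- 301 + 99 * u[rows] },
      hdl_outlier = { cov$hdl[rows] <- 101 + 49 * u[rows] },
      bmi_outlier = { cov$bmi[rows] <- 101 + 29 * u[rows] },
      ldl_outlier = { cov$ldl[rows] <- 1001 + 499 * u[rows] },
      tg_outlier = { cov$triglycerides[rows] <- 1501 + 499 * u[rows] }
    )
  }
  simulate_outcomes(cov, outcome_spec("subtype_hazards"), seed = seed + 2L)
}
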