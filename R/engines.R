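# Risk engines: term vocabulary, coefficient tables, scoring, sex transfer.
#
# An engine is a Cox-type equation risk = 1 - S0^exp(L), where L is a
# mean-centered linear combination of (log-)transformed covariates. Terms
# may be conditional (treated vs untreated systolic blood pressure) so that
# exactly one of the pair contributes to any one record.

.transforms <- c("ln", "identity", "ln_square", "product_of_lns", "ln_times")

#' Construct a single risk-equation term
#'
#' @param name Term name (e.g. `"ln_age"`).
#' @param covariates One or two cohort column names.
#' @param transform One of `"ln"`, `"identity"`, `"ln_square"`,
#'   `"product_of_lns"` (log(x1) * log(x2)), `"ln_times"` (log(x1) * x2,
#'   for log-age-by-indicator interactions).
#' @param beta Coefficient.
#' @param condition_field,condition_value Optional gating: the term
#'   contributes only to records where `record[[condition_field]] ==
#'   condition_value` (used for the treated/untreated SBP pair).
#' @return A `risk_term` list.
#' @export
risk_term <- function(name, covariates, transform, beta,
                      condition_field = NULL, condition_value = NULL) {
  transform <- match.arg(transform, .transforms)
  n_cov <- switch(transform, product_of_lns = 2L, ln_times = 2L, 1L)
  if (length(covariates) != n_cov) {
    abort(sprintf("transform `%s` needs %d covariate(s)", transform, n_cov))
  }
  if (!is.null(condition_field) && is.null(condition_value)) {
    abort("`condition_value` required with `condition_field`")
  }
  structure(
    list(
      name = name, covariates = covariates, transform = transform,
      beta = beta, condition_field = condition_field,
      condition_value = condition_value
    ),
    class = "risk_term"
  )
}

# Vector of the raw (coefficient-free) transformed covariate values for one
# term over a cohort; errors name the covariate on non-positive log input.
term_value <- function(term, cohort) {
  x1 <- as.numeric(cohort[[term$covariates[1]]])
  ln1 <- function() {
    if (any(x1 <= 0)) {
      abort(sprintf("non-positive value of `%s` under a log transform", term$covariates[1]))
    }
    log(x1)
  }
  val <- switch(term$transform,
    identity = x1,
    ln = ln1(),
    ln_square = ln1()^2,
    product_of_lns = {
      x2 <- as.numeric(cohort[[term$covariates[2]]])
      if (any(x2 <= 0)) {
        abort(sprintf("non-positive value of `%s` under a log transform", term$covariates[2]))
      }
      ln1() * log(x2)
    },
    ln_times = ln1() * as.numeric(cohort[[term$covariates[2]]])
  )
  if (!is.null(term$condition_field)) {
    gate <- as.numeric(cohort[[term$condition_field]]) == term$condition_value
    val <- val * as.numeric(gate)
  }
  val
}

#' Construct a risk-engine specification
#'
#' @param engine `"framingham"`, `"ascvd"` or `"custom"`.
#' @param sex `"male"` or `"female"` (the sex whose coefficients these are).
#' @param terms List of [risk_term()] objects.
#' @param mean_lp The mean linear predictor subtracted before
#'   exponentiation (the published "Mean(Coefficient x Value)" offset).
#' @param baseline_survival 10-year event-free survival at the mean
#'   covariate profile, in (0, 1).
#' @return A `risk_engine_spec` object.
#' @export
risk_engine_spec <- function(engine, sex, terms, mean_lp, baseline_survival) {
  stopifnot(engine %in% c("framingham", "ascvd", "custom"))
  stopifnot(sex %in% c("male", "female"))
  if (length(terms) == 0) abort("`terms` must be non-empty")
  if (!all(vapply(terms, inherits, logical(1), "risk_term"))) {
    abort("`terms` must be a list of risk_term objects")
  }
  if (!is.finite(mean_lp)) abort("`mean_lp` must be finite")
  if (!(baseline_survival > 0 && baseline_survival < 1)) {
    abort("`baseline_survival` must lie strictly inside (0, 1)")
  }
  names(terms) <- vapply(terms, `[[`, character(1), "name")
  structure(
    list(
      engine = engine, sex = sex, terms = terms, mean_lp = mean_lp,
      baseline_survival = baseline_survival
    ),
    class = "risk_engine_spec"
  )
}

#' @export
print.risk_engine_spec <- function(x, ...) {
  cat(sprintf(
    "<risk_engine_spec> %s / %s coefficients: %d terms, mean_lp = %.4f, S0(10y) = %.5f\n",
    x$engine, x$sex, length(x$terms), x$mean_lp, x$baseline_survival
  ))
  print(tidy(x))
  invisible(x)
}

#' Read a coefficient table into a risk-engine spec
#'
#' The table is a CSV with columns `term, covariate1, covariate2,
#' transform, condition_field, condition_value, beta` plus two footer rows
#' named `mean_lp` and `baseline_survival` carrying those scalars in the
#' `beta` column.
#'
#' @param path Path to the coefficient CSV.
#' @param engine,sex Labels recorded on the spec.
#' @return A `risk_engine_spec`.
#' @export
read_engine_spec <- function(path, engine = "custom", sex = "male") {
  tab <- readr::read_csv(path, show_col_types = FALSE, col_types = readr::cols(
    term = readr::col_character(), covariate1 = readr::col_character(),
    covariate2 = readr::col_character(), transform = readr::col_character(),
    condition_field = readr::col_character(),
    condition_value = readr::col_double(), beta = readr::col_double()
  ))
  meta <- tab$term %in% c("mean_lp", "baseline_survival")
  scalars <- setNames(tab$beta[meta], tab$term[meta])
  if (!all(c("mean_lp", "baseline_survival") %in% names(scalars))) {
    abort("coefficient table is missing its mean_lp / baseline_survival footer rows")
  }
  rows <- tab[!meta, , drop = FALSE]
  terms <- purrr::pmap(rows, function(term, covariate1, covariate2, transform,
                                      condition_field, condition_value, beta) {
    covs <- c(covariate1, covariate2)
    covs <- covs[!is.na(covs)]
    risk_term(
      name = term, covariates = covs, transform = transform, beta = beta,
      condition_field = if (is.na(condition_field)) NULL else condition_field,
      condition_value = if (is.na(condition_value)) NULL else condition_value
    )
  })
  risk_engine_spec(engine, sex, terms, scalars[["mean_lp"]],
                   scalars[["baseline_survival"]])
}

#' Write a risk-engine spec back to its coefficient-table form
#'
#' @param spec A `risk_engine_spec`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_engine_spec <- function(spec, path) {
  rows <- purrr::map_dfr(spec$terms, function(tm) {
    tibble::tibble(
      term = tm$name,
      covariate1 = tm$covariates[1],
      covariate2 = if (length(tm$covariates) > 1) tm$covariates[2] else NA_character_,
      transform = tm$transform,
      condition_field = tm$condition_field %||% NA_character_,
      condition_value = tm$condition_value %||% NA_real_,
      beta = tm$beta
    )
  })
  foot <- tibble::tibble(
    term = c("mean_lp", "baseline_survival"),
    covariate1 = NA_character_, covariate2 = NA_character_,
    transform = NA_character_, condition_field = NA_character_,
    condition_value = NA_real_,
    beta = c(spec$mean_lp, spec$baseline_survival)
  )
  readr::write_csv(dplyr::bind_rows(rows, foot), path, na = "")
  invisible(path)
}

#' Packaged risk-engine coefficient tables
#'
#' Returns the sex-specific coefficient set for the general-CVD Framingham
#' risk score (D'Agostino et al. 2008) or the pooled cohort ASCVD
#' equations (Goff et al. 2013; White/other stratum), read from the
#' package's auditable coefficient CSVs.
#'
#' @param engine `"framingham"` or `"ascvd"`.
#' @param sex `"male"` or `"female"`.
#' @return A `risk_engine_spec`.
#' @export
builtin_spec <- function(engine = c("framingham", "ascvd"),
                         sex = c("male", "female")) {
  engine <- match.arg(engine)
  sex <- match.arg(sex)
  path <- system.file(
    "extdata", "coefficients", sprintf("%s_%s.csv", engine, sex),
    package = "riskbench", mustWork = TRUE
  )
  read_engine_spec(path, engine = engine, sex = sex)
}

#' Mean-centered linear predictor under a risk-engine spec
#'
#' Computes `L = sum_k beta_k f_k(record) - mean_lp` for every record.
#' Covariates outside an engine's development range are scored as-is with
#' a warning rather than truncated.
#'
#' @param cohort A data frame of participant records (need not carry
#'   outcome columns).
#' @param spec A `risk_engine_spec`.
#' @return Numeric vector of linear predictors.
#' @export
linear_predictor <- function(cohort, spec) {
  stopifnot(inherits(spec, "risk_engine_spec"))
  contrib <- term_matrix(cohort, spec$terms)
  rowSums(contrib) - spec$mean_lp
}

# n x n_terms matrix of beta_k * f_k(record) contributions.
term_matrix <- function(cohort, terms) {
  vals <- vapply(
    terms, function(tm) tm$beta * term_value(tm, cohort),
    numeric(nrow(cohort))
  )
  if (nrow(cohort) == 1L) vals <- matrix(vals, nrow = 1, dimnames = list(NULL, names(terms)))
  vals
}

#' Predict 10-year risk for every record in a cohort
#'
#' `risk = 1 - S0^exp(L)`, clamped to `[0, 1]` only against floating-point
#' spill; strictly increasing in the linear predictor.
#'
#' @param cohort A data frame of participant records.
#' @param spec A `risk_engine_spec`.
#' @return A tibble with columns `id`, `linear_predictor`, `risk`.
#' @export
predict_risk <- function(cohort, spec) {
  lp <- linear_predictor(cohort, spec)
  risk <- 1 - spec$baseline_survival^exp(lp)
  tibble::tibble(
    id = if ("id" %in% names(cohort)) cohort$id else as.character(seq_len(nrow(cohort))),
    linear_predictor = lp,
    risk = pmin(pmax(risk, 0), 1)
  )
}

#' Relabel a spec for the opposite sex (coefficient transfer)
#'
#' Scoring a female cohort with the male coefficient set (terms,
#' mean-centering offset and baseline survival all unchanged) is the
#' cross-sex transfer experiment used to diagnose sex-specific
#' miscalibration.
#'
#' @param spec A `risk_engine_spec`.
#' @param target_sex `"male"` or `"female"`.
#' @return The same spec labelled for `target_sex`.
#' @export
transfer_spec <- function(spec, target_sex = c("male", "female")) {
  target_sex <- match.arg(target_sex)
  stopifnot(inherits(spec, "risk_engine_spec"))
  out <- spec
  out$sex <- target_sex
  out
}

#' @export
tidy.risk_engine_spec <- function(x, ...) {
  purrr::map_dfr(x$terms, function(tm) {
    tibble::tibble(
      term = tm$name,
      covariates = paste(tm$covariates, collapse = ":"),
      transform = tm$transform,
      condition = if (is.null(tm$condition_field)) NA_character_ else
        sprintf("%s == %s", tm$condition_field, tm$condition_value),
      beta = tm$beta
    )
  })
}

#' @export
glance.risk_engine_spec <- function(x, ...) {
  tibble::tibble(
    engine = x$engine, sex = x$sex, n_terms = length(x$terms),
    mean_lp = x$mean_lp, baseline_survival = x$baseline_survival
  )
}
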