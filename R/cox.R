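# Cox proportional-hazards fitting on the risk-term design.
#
# The partial likelihood is maximized by survival::coxph with Breslow tie
# handling; the 10-year baseline survival is taken from the Breslow
# cumulative hazard evaluated at the mean linear predictor, so a fit can be
# packaged as a scoring engine in the same 1 - S0^exp(L - mean_lp) form as
# the published equations.

#' Fit a Cox model over a list of risk terms
#'
#' @param cohort A validated cohort with `followup_years` and `event`.
#' @param terms A list of [risk_term()] objects defining the design columns
#'   (their `beta` slots are ignored; the fit estimates them).
#' @param ties Tie handling for the partial likelihood, `"breslow"`
#'   (default) or `"efron"`.
#' @return A `cox_fit` object with elements `terms` (betas filled in from
#'   the fit), `coefficients`, `se`, `baseline_survival_10y` (at the mean
#'   covariate profile), `mean_lp`, `convergence`, and
#'   `log_partial_likelihood`.
#' @export
fit_cox <- function(cohort, terms, ties = c("breslow", "efron")) {
  ties <- match.arg(ties)
  cohort <- validate_cohort(cohort)
  ev <- as.logical(cohort$event)
  if (!any(ev)) abort("cannot fit a Cox model on a cohort with no events")
  if (length(terms) == 0) abort("`terms` must be non-empty")
  names(terms) <- vapply(terms, `[[`, character(1), "name")
  x <- vapply(terms, function(tm) term_value(tm, cohort), numeric(nrow(cohort)))
  x <- matrix(x, nrow = nrow(cohort), dimnames = list(NULL, names(terms)))
  ctrl <- survival::coxph.control(eps = 1e-9, iter.max = 100)
  fit <- survival::coxph(
    survival::Surv(cohort$followup_years, ev) ~ x,
    ties = ties, control = ctrl
  )
  beta <- unname(fit$coefficients)
  dropped <- is.na(beta)
  beta[dropped] <- 0  # constant columns carry no information
  se <- sqrt(diag(fit$var))
  se_full <- rep(NA_real_, length(beta))
  se_full[!dropped] <- se[seq_len(sum(!dropped))]
  lp <- drop(x %*% beta)
  mean_lp <- mean(lp)
  bh <- survival::basehaz(fit, centered = FALSE)
  in_window <- bh$time <= 10
  h0_10 <- if (any(in_window)) max(bh$hazard[in_window]) else 0
  s0 <- exp(-h0_10 * exp(mean_lp))
  s0 <- min(max(s0, .Machine$double.eps), 1 - .Machine$double.eps)
  fitted_terms <- purrr::map2(terms, beta, function(tm, b) { tm$beta <- b; tm })
  structure(
    list(
      terms = fitted_terms,
      coefficients = setNames(beta, names(terms)),
      se = setNames(se_full, names(terms)),
      baseline_survival_10y = s0,
      mean_lp = mean_lp,
      convergence = if (fit$iter < ctrl$iter.max) "converged" else "max_iter",
      iterations = fit$iter,
      log_partial_likelihood = fit$loglik[length(fit$loglik)],
      null_log_partial_likelihood = fit$loglik[1],
      n = nrow(cohort), n_events = sum(ev), ties = ties
    ),
    class = "cox_fit"
  )
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf(
    "<cox_fit> %d terms, n = %d (%d events), %s in %d iterations; S0(10y at mean) = %.5f\n",
    length(x$coefficients), x$n, x$n_events, x$convergence, x$iterations,
    x$baseline_survival_10y
  ))
  print(tidy(x))
  invisible(x)
}

#' @export
tidy.cox_fit <- function(x, ...) {
  est <- x$coefficients
  se <- x$se
  tibble::tibble(
    term = names(est),
    estimate = unname(est),
    std.error = unname(se),
    statistic = unname(est / se),
    p.value = 2 * pnorm(-abs(unname(est / se)))
  )
}

#' @export
glance.cox_fit <- function(x, ...) {
  tibble::tibble(
    n = x$n, n_events = x$n_events,
    log_partial_likelihood = x$log_partial_likelihood,
    null_log_partial_likelihood = x$null_log_partial_likelihood,
    baseline_survival_10y = x$baseline_survival_10y,
    mean_lp = x$mean_lp,
    convergence = x$convergence
  )
}

#' Package a Cox fit as a risk-engine spec
#'
#' @param fit A `cox_fit`.
#' @param sex Sex label for the resulting spec.
#' @return A `risk_engine_spec` scoring `1 - S0^exp(L - mean_lp)` with the
#'   fitted coefficients and baseline survival.
#' @export
as_engine_spec <- function(fit, sex = "male") {
  stopifnot(inherits(fit, "cox_fit"))
  risk_engine_spec(
    engine = "custom", sex = sex, terms = fit$terms,
    mean_lp = fit$mean_lp, baseline_survival = fit$baseline_survival_10y
  )
}
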