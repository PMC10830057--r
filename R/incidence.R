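# Person-year incidence rates and two-sample rate comparison.

#' Incidence rate per 100,000 person-years with exact Poisson interval
#'
#' The confidence interval uses the exact Poisson (chi-square quantile)
#' method on the event count: with `x` events, the lower bound is
#' `qchisq(alpha/2, 2x) / 2` and the upper `qchisq(1 - alpha/2, 2x + 2) / 2`,
#' both scaled by person-years. Zero events give a lower bound of exactly 0.
#'
#' @param events Non-negative event count.
#' @param person_years Total follow-up time in years (> 0).
#' @param ci_level Confidence level, default 0.95.
#' @return A one-row tibble: `events`, `person_years`, `rate`, `ci_low`,
#'   `ci_high` (all rates per 100,000 person-years), `ci_level`.
#' @export
incidence_rate <- function(events, person_years, ci_level = 0.95) {
  stopifnot(length(events) == 1, length(person_years) == 1)
  if (!is.finite(person_years) || person_years <= 0) {
    abort("`person_years` must be strictly positive")
  }
  if (!is.finite(events) || events < 0) abort("`events` must be non-negative")
  alpha <- 1 - ci_level
  scale <- 1e5 / person_years
  lower <- if (events == 0) 0 else qchisq(alpha / 2, 2 * events) / 2
  upper <- qchisq(1 - alpha / 2, 2 * events + 2) / 2
  tibble::tibble(
    events = events,
    person_years = person_years,
    rate = events * scale,
    ci_low = lower * scale,
    ci_high = upper * scale,
    ci_level = ci_level
  )
}

#' Per-subtype incidence table for a cohort
#'
#' Person-years are the summed follow-up of the whole cohort (time to first
#' event or 10-year administrative censoring); each composite subtype's
#' events are counted by ICD-10 category.
#'
#' @param cohort A validated cohort.
#' @param ci_level Confidence level for the per-subtype Poisson intervals.
#' @return A tibble with one row per observed subtype category, ordered by
#'   decreasing rate.
#' @export
incidence_table <- function(cohort, ci_level = 0.95) {
  cohort <- validate_cohort(cohort)
  py <- sum(cohort$followup_years)
  codes <- cohort$event_code[as.logical(cohort$event)]
  if (length(codes) == 0) {
    return(tibble::tibble(
      category = character(), subtype = character(), events = integer(),
      person_years = numeric(), rate = numeric(), ci_low = numeric(),
      ci_high = numeric(), ci_level = numeric()
    ))
  }
  mapped <- map_outcome(codes)
  counts <- table(mapped$category)
  out <- purrr::map_dfr(names(counts), function(cat) {
    dplyr::bind_cols(
      tibble::tibble(
        category = cat,
        subtype = unname(composite_cvd_codes()[cat])
      ),
      incidence_rate(as.integer(counts[[cat]]), py, ci_level)
    )
  })
  dplyr::arrange(out, dplyr::desc(.data$rate))
}

#' Compare two incidence rates (exact conditional test)
#'
#' Conditions on the total number of events: under equal rates the events
#' in group A are binomial with success probability equal to A's share of
#' the person-years, giving the standard exact two-sample Poisson rate
#' comparison. Two zero-event groups return p = 1.
#'
#' @param a,b One-row tibbles from [incidence_rate()] (or any list with
#'   `events` and `person_years`).
#' @return A one-row tibble with the two rates, their ratio and the
#'   two-sided `p_value`.
#' @export
rate_ratio_test <- function(a, b) {
  xa <- a$events; xb <- b$events
  pya <- a$person_years; pyb <- b$person_years
  stopifnot(xa >= 0, xb >= 0, pya > 0, pyb > 0)
  total <- xa + xb
  p0 <- pya / (pya + pyb)
  p <- if (total == 0) 1 else binom.test(xa, total, p = p0)$p.value
  tibble::tibble(
    rate_a = xa / pya * 1e5,
    rate_b = xb / pyb * 1e5,
    rate_ratio = ifelse(xb == 0, NA_real_, (xa / pya) / (xb / pyb)),
    p_value = p
  )
}
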