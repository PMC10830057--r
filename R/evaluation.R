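# Discrimination and calibration statistics.
#
# AUC and its variance follow DeLong's structural-component (placement)
# estimator; ties count one half. Calibration uses the decile
# Hosmer-Lemeshow chi-square on 10-year binary outcomes.

check_labels <- function(labels) {
  labels <- as.logical(labels)
  if (any(is.na(labels))) abort("`labels` must be logical or 0/1 without NAs")
  if (!any(labels) || all(labels)) {
    abort("both outcome classes must be present")
  }
  labels
}

# Placement values: for each positive, the fraction of negatives scored
# below it (ties one half), and symmetrically for negatives. Computed from
# midranks (O(n log n)) rather than the n1 x n0 comparison matrix.
placements <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  n1 <- length(pos); n0 <- length(neg)
  r_all <- rank(scores, ties.method = "average")
  r_pos <- rank(pos, ties.method = "average")
  r_neg <- rank(neg, ties.method = "average")
  v10 <- (r_all[labels] - r_pos) / n0
  v01 <- 1 - (r_all[!labels] - r_neg) / n1
  list(v10 = v10, v01 = v01, auc = mean(v10))
}

#' ROC area under the curve with DeLong variance
#'
#' AUC is the Mann-Whitney probability that a random event record scores
#' above a random non-event record (ties counted one half). The standard
#' error comes from DeLong's placement components and the confidence
#' interval is the normal-approximation interval clipped to `[0, 1]`.
#' The reported sensitivity/specificity pair is the Youden-optimal
#' operating point from [operating_point()].
#'
#' @param scores Numeric risk scores.
#' @param labels Logical (or 0/1) event indicators aligned to `scores`.
#' @param ci_level Confidence level, default 0.95.
#' @return A `roc_result` object; see [tidy()] / [glance()] methods.
#' @export
roc_auc <- function(scores, labels, ci_level = 0.95) {
  labels <- check_labels(labels)
  stopifnot(length(scores) == length(labels), all(is.finite(scores)))
  pl <- placements(scores, labels)
  n1 <- sum(labels); n0 <- sum(!labels)
  v10 <- if (n1 > 1) var(pl$v10) else 0
  v01 <- if (n0 > 1) var(pl$v01) else 0
  se <- sqrt(v10 / n1 + v01 / n0)
  z <- qnorm(1 - (1 - ci_level) / 2)
  op <- operating_point(scores, labels)
  structure(
    list(
      auc = pl$auc, se = se,
      ci_low = max(0, pl$auc - z * se), ci_high = min(1, pl$auc + z * se),
      ci_level = ci_level,
      sensitivity = op$sensitivity, specificity = op$specificity,
      threshold = op$threshold,
      n_pos = n1, n_neg = n0
    ),
    class = "roc_result"
  )
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf(
    "<roc_result> AUC %.3f (%.0f%% CI %.3f-%.3f); sens %.1f / spec %.1f at threshold %.4g; %d events / %d non-events\n",
    x$auc, 100 * x$ci_level, x$ci_low, x$ci_high,
    x$sensitivity, x$specificity, x$threshold, x$n_pos, x$n_neg
  ))
  invisible(x)
}

#' @export
tidy.roc_result <- function(x, ...) {
  tibble::tibble(
    auc = x$auc, se = x$se, ci_low = x$ci_low, ci_high = x$ci_high,
    sensitivity = x$sensitivity, specificity = x$specificity,
    threshold = x$threshold
  )
}

#' @export
glance.roc_result <- function(x, ...) {
  tibble::tibble(auc = x$auc, se = x$se, n_pos = x$n_pos, n_neg = x$n_neg)
}

#' Paired DeLong test for two correlated AUCs
#'
#' Both score vectors are evaluated on the same records, so the AUC
#' difference variance includes the covariance of the placement
#' components: `z = (auc_a - auc_b) / sqrt(var_a + var_b - 2 cov_ab)`,
#' with a two-sided normal p-value.
#'
#' @param scores_a,scores_b Paired score vectors.
#' @param labels Shared event labels.
#' @return A `delong_comparison` object.
#' @export
delong_test <- function(scores_a, scores_b, labels) {
  labels <- check_labels(labels)
  stopifnot(length(scores_a) == length(labels), length(scores_b) == length(labels))
  pa <- placements(scores_a, labels)
  pb <- placements(scores_b, labels)
  n1 <- sum(labels); n0 <- sum(!labels)
  var_a <- var(pa$v10) / n1 + var(pa$v01) / n0
  var_b <- var(pb$v10) / n1 + var(pb$v01) / n0
  cov_ab <- stats::cov(pa$v10, pb$v10) / n1 + stats::cov(pa$v01, pb$v01) / n0
  var_diff <- var_a + var_b - 2 * cov_ab
  diff <- pa$auc - pb$auc
  if (var_diff <= .Machine$double.eps^0.5) {
    if (abs(diff) < .Machine$double.eps^0.5) {
      z <- 0; p <- 1
    } else {
      abort("degenerate DeLong comparison: zero variance with unequal AUCs")
    }
  } else {
    z <- diff / sqrt(var_diff)
    p <- 2 * pnorm(-abs(z))
  }
  structure(
    list(
      auc_a = pa$auc, auc_b = pb$auc, var_a = var_a, var_b = var_b,
      cov_ab = cov_ab, z = z, p_value = p
    ),
    class = "delong_comparison"
  )
}

#' @export
print.delong_comparison <- function(x, ...) {
  cat(sprintf(
    "<delong_comparison> AUC %.3f vs %.3f; z = %.3f, p = %.4g\n",
    x$auc_a, x$auc_b, x$z, x$p_value
  ))
  invisible(x)
}

#' @export
tidy.delong_comparison <- function(x, ...) {
  tibble::tibble(
    auc_a = x$auc_a, auc_b = x$auc_b, auc_diff = x$auc_a - x$auc_b,
    var_a = x$var_a, var_b = x$var_b, cov_ab = x$cov_ab,
    z = x$z, p_value = x$p_value
  )
}

#' Hosmer-Lemeshow decile calibration
#'
#' Records are sorted by predicted risk and cut at risk quantiles into
#' `bins` near-equal groups; tied predictions stay together in the lower
#' bin. Per group, the expected events are the summed predicted risks and
#' the default statistic is the Hosmer-Lemeshow form
#' `sum (O - E)^2 / (E (1 - E/n))` on `bins - 2` degrees of freedom; the
#' plain Pearson `sum (O - E)^2 / E` form is available via `variant`.
#'
#' @param predictions Predicted risk fractions in `[0, 1]`.
#' @param labels Logical (or 0/1) observed outcomes.
#' @param bins Number of groups, default 10.
#' @param variant `"hosmer-lemeshow"` (default) or `"pearson"`.
#' @return An `hl_report` with the per-bin table and the chi-square test.
#' @export
hosmer_lemeshow <- function(predictions, labels, bins = 10,
                            variant = c("hosmer-lemeshow", "pearson")) {
  variant <- match.arg(variant)
  labels <- as.logical(labels)
  stopifnot(bins >= 2, length(predictions) == length(labels))
  if (length(predictions) < bins) abort("need at least `bins` records")
  qs <- stats::quantile(predictions, probs = seq(0, 1, length.out = bins + 1),
                        names = FALSE, type = 7)
  breaks <- unique(qs)
  if (length(breaks) - 1 < bins) {
    warn(sprintf(
      "tied predictions collapse the grouping to %d bins", length(breaks) - 1
    ))
  }
  if (length(breaks) < 2) breaks <- c(breaks - 0.5, breaks + 0.5)
  grp <- cut(predictions, breaks = breaks, include.lowest = TRUE, labels = FALSE)
  tab <- tibble::tibble(bin = grp, risk = predictions, obs = as.numeric(labels)) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_predicted_risk = mean(.data$risk),
      expected_events = sum(.data$risk),
      observed_events = sum(.data$obs),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$bin)
  o <- tab$observed_events; e <- tab$expected_events; n <- tab$n
  denom <- switch(variant,
    "hosmer-lemeshow" = e * (1 - e / n),
    "pearson" = e
  )
  terms <- (o - e)^2 / denom
  if (any(denom <= 0 & (o - e)^2 > 0)) {
    warn("a bin has zero expected-variance denominator; chi-square is infinite")
    chi2 <- Inf
  } else {
    chi2 <- sum(terms[denom > 0])
  }
  df <- nrow(tab) - 2
  structure(
    list(
      bins = tab, chi_square = chi2, df = df,
      p_value = pchisq(chi2, df, lower.tail = FALSE),
      variant = variant,
      overall_predicted_pct = 100 * mean(predictions),
      overall_observed_pct = 100 * mean(labels)
    ),
    class = "hl_report"
  )
}

#' @export
print.hl_report <- function(x, ...) {
  cat(sprintf(
    "<hl_report> chi-square %.3f on %d df, p = %.4g (%s form); predicted %.2f%% vs observed %.2f%%\n",
    x$chi_square, x$df, x$p_value, x$variant,
    x$overall_predicted_pct, x$overall_observed_pct
  ))
  print(x$bins)
  invisible(x)
}

#' @export
tidy.hl_report <- function(x, ...) x$bins

#' @export
glance.hl_report <- function(x, ...) {
  tibble::tibble(
    chi_square = x$chi_square, df = x$df, p_value = x$p_value,
    overall_predicted_pct = x$overall_predicted_pct,
    overall_observed_pct = x$overall_observed_pct
  )
}

#' Youden-optimal operating point
#'
#' Scans every observed score as a threshold (predict positive when
#' `score >= threshold`) and returns the point maximizing Youden's
#' J = sensitivity + specificity - 1; ties are broken towards higher
#' sensitivity.
#'
#' @inheritParams roc_auc
#' @return A one-row tibble: `sensitivity`, `specificity` (percent),
#'   `threshold`, `youden_j`.
#' @export
operating_point <- function(scores, labels) {
  labels <- check_labels(labels)
  thresholds <- sort(unique(scores))
  n1 <- sum(labels); n0 <- sum(!labels)
  idx <- match(scores, thresholds)
  pos_at <- tabulate(idx[labels], nbins = length(thresholds))
  neg_at <- tabulate(idx[!labels], nbins = length(thresholds))
  # counts with score >= each threshold
  tp <- rev(cumsum(rev(pos_at)))
  fp <- rev(cumsum(rev(neg_at)))
  sens <- tp / n1
  spec <- 1 - fp / n0
  j <- sens + spec - 1
  best <- which(j == max(j))
  if (length(best) > 1) best <- best[which.max(sens[best])]
  tibble::tibble(
    sensitivity = 100 * sens[best],
    specificity = 100 * spec[best],
    threshold = thresholds[best],
    youden_j = j[best]
  )
}

#' Evaluate a prediction column against an outcome column
#'
#' Data-frame-first wrapper combining discrimination and calibration: AUC
#' with DeLong interval, the Youden operating point, and the decile
#' Hosmer-Lemeshow table.
#'
#' @param data A data frame holding predictions and outcomes.
#' @param risk,event Tidy-eval columns with the predicted risk fraction and
#'   the observed binary outcome (defaults `risk` and `event`).
#' @param bins,variant Passed to [hosmer_lemeshow()].
#' @return A list with elements `roc` (a `roc_result`) and `calibration`
#'   (an `hl_report`).
#' @export
evaluate_predictions <- function(data, risk = "risk", event = "event",
                                 bins = 10, variant = "hosmer-lemeshow") {
  scores <- data[[risk]]
  labels <- as.logical(data[[event]])
  list(
    roc = roc_auc(scores, labels),
    calibration = hosmer_lemeshow(scores, labels, bins = bins, variant = variant)
  )
}
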