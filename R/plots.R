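# ggplot2 methods for the evaluation result types.

#' Calibration bar chart for a Hosmer-Lemeshow report
#'
#' Paired vertical bars of observed and predicted event proportions per
#' risk decile, the standard calibration display for 10-year risk
#' equations.
#'
#' @param object An `hl_report` from [hosmer_lemeshow()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hl_report <- function(object, ...) {
  dat <- object$bins |>
    dplyr::mutate(
      observed = 100 * .data$observed_events / .data$n,
      predicted = 100 * .data$expected_events / .data$n
    ) |>
    tidyr::pivot_longer(c("observed", "predicted"),
                        names_to = "series", values_to = "pct")
  ggplot2::ggplot(dat, ggplot2::aes(
    x = factor(.data$bin), y = .data$pct, fill = .data$series
  )) +
    ggplot2::geom_col(position = ggplot2::position_dodge()) +
    ggplot2::scale_fill_manual(values = c(observed = "grey10", predicted = "grey65")) +
    ggplot2::labs(
      x = "Risk decile", y = "10-year event rate (%)", fill = NULL,
      subtitle = sprintf(
        "Hosmer-Lemeshow chi-square %.2f on %d df, p = %.3g",
        object$chi_square, object$df, object$p_value
      )
    ) +
    ggplot2::theme_minimal()
}

#' Variance-importance bar chart
#'
#' @param object An importance tibble from [variance_importance()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_importance <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(
    x = .data$variance_share,
    y = stats::reorder(.data$term, .data$variance_share)
  )) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::facet_grid(model ~ sex) +
    ggplot2::labs(x = "Variance share of linear predictor (%)", y = NULL) +
    ggplot2::theme_minimal()
}
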