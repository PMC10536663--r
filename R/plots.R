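#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a spectrum
#'
#' Power versus frequency up to Nyquist, on a square-root scale so the
#' gait harmonics remain visible next to the DC (gravity) bin.
#'
#' @param object A `gait_spectrum`.
#' @param f_max Upper frequency limit for the plot, Hz. Default 10.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot gait_spectrum
#' @export
autoplot.gait_spectrum <- function(object, f_max = 10, ...) {
  n <- attr(object, "N")
  df <- as_tibble(object)[object$k <= floor(n / 2) & object$freq <= f_max, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$freq, y = .data$power)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_sqrt() +
    ggplot2::labs(x = "frequency (Hz)", y = "power |coef|^2") +
    ggplot2::theme_minimal()
}

#' Plot a longitudinal gait trend
#'
#' One point per walk, the fitted regression line and the pointwise
#' confidence band for the mean response.
#'
#' @param object A `gait_trend` from [trend_fit()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot gait_trend
#' @export
autoplot.gait_trend <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$days, y = .data$value)) +
    ggplot2::geom_ribbon(
      data = object$band,
      ggplot2::aes(x = .data$days, ymin = .data$lower, ymax = .data$upper),
      inherit.aes = FALSE, alpha = 0.2
    ) +
    ggplot2::geom_line(
      data = object$band,
      ggplot2::aes(x = .data$days, y = .data$fit), inherit.aes = FALSE
    ) +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "days since first walk", y = object$index,
      title = sprintf("%s trend (%g%% pointwise band)", object$index, 100 * object$conf)
    ) +
    ggplot2::theme_minimal()
}

#' Bar chart of per-participant entropy variation
#'
#' Percentage entropy variation per participant, signed: bars below zero
#' are improvements, above zero deteriorations.
#'
#' @param summary A participant summary tibble with `participant` and
#'   `variation_pct` (from [summarize_participants()] or
#'   [gait_study_table()]).
#' @return A ggplot.
#' @export
plot_cohort_variation <- function(summary) {
  ggplot2::ggplot(
    summary,
    ggplot2::aes(
      x = factor(.data$participant), y = .data$variation_pct,
      fill = .data$variation_pct > 0
    )
  ) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "#2c7fb8", `TRUE` = "#d95f0e")) +
    ggplot2::labs(x = "participant", y = "entropy variation (%)") +
    ggplot2::theme_minimal()
}
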