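# ggplot2 visualizations for melt curves, difference plots, amplification
# traces and association forest plots.

#' Plot normalized melt curves
#'
#' @param curves Long tibble with `temperature`, `normalized`, and a grouping
#'   column (default `sample_id`); an optional `genotype` column colors the
#'   curves.
#' @param color Column to color by (tidy-eval), default `genotype` if present.
#' @return A ggplot object.
#' @export
plot_melt_curves <- function(curves, color = NULL) {
  color_quo <- rlang::enquo(color)
  if (rlang::quo_is_null(color_quo) && "genotype" %in% names(curves)) {
    color_quo <- rlang::quo(.data$genotype)
  }
  group_col <- intersect(c("well", "sample_id"), names(curves))[1]
  p <- ggplot2::ggplot(curves, ggplot2::aes(.data$temperature, .data$normalized))
  if (!rlang::quo_is_null(color_quo)) {
    p <- p + ggplot2::geom_line(ggplot2::aes(group = .data[[group_col]],
                                             color = !!color_quo), alpha = 0.7)
  } else {
    p <- p + ggplot2::geom_line(ggplot2::aes(group = .data[[group_col]]), alpha = 0.7)
  }
  p + ggplot2::labs(x = "Temperature (°C)", y = "Normalized fluorescence") +
    ggplot2::theme_minimal()
}

#' Plot difference curves against a reference
#'
#' @param residuals Long tibble with `temperature`, `residual` and a grouping
#'   column (`sample_id` or `well`), optionally `genotype`.
#' @return A ggplot object.
#' @export
plot_difference_curves <- function(residuals) {
  group_col <- intersect(c("well", "sample_id"), names(residuals))[1]
  aes <- if ("genotype" %in% names(residuals)) {
    ggplot2::aes(.data$temperature, .data$residual,
                 group = .data[[group_col]], color = .data$genotype)
  } else {
    ggplot2::aes(.data$temperature, .data$residual, group = .data[[group_col]])
  }
  ggplot2::ggplot(residuals, aes) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, color = "grey50") +
    ggplot2::geom_line(alpha = 0.7) +
    ggplot2::labs(x = "Temperature (°C)", y = "Δ normalized fluorescence") +
    ggplot2::theme_minimal()
}

#' Plot amplification curves
#'
#' @param curves Long tibble with `cycle`, `fluorescence`, `well` (or
#'   `sample_id`), optionally `allele_primer` for coloring.
#' @param threshold Optional horizontal threshold line.
#' @return A ggplot object.
#' @export
plot_amplification <- function(curves, threshold = NULL) {
  group_col <- intersect(c("well", "sample_id"), names(curves))[1]
  aes <- if ("allele_primer" %in% names(curves)) {
    ggplot2::aes(.data$cycle, .data$fluorescence,
                 group = .data[[group_col]], color = .data$allele_primer)
  } else {
    ggplot2::aes(.data$cycle, .data$fluorescence, group = .data[[group_col]])
  }
  p <- ggplot2::ggplot(curves, aes) + ggplot2::geom_line(alpha = 0.7)
  if (!is.null(threshold)) {
    p <- p + ggplot2::geom_hline(yintercept = threshold, linetype = 2)
  }
  p + ggplot2::labs(x = "Cycle", y = "Fluorescence (a.u.)") +
    ggplot2::theme_minimal()
}

#' Forest plot of an association report
#'
#' Odds ratios with their confidence intervals per comparison, log-scaled.
#'
#' @param object An `snp_assoc` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot snp_assoc
#' @export
autoplot.snp_assoc <- function(object, ...) {
  if (object$monomorphic || nrow(object$results) == 0L) {
    snpmelt_abort("nothing to plot: monomorphic locus", "invalid_input")
  }
  df <- object$results
  ggplot2::ggplot(df, ggplot2::aes(.data$odds_ratio,
                                   stats::reorder(.data$comparison, .data$odds_ratio))) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2, color = "grey50") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_low, xmax = .data$ci_high),
                            height = 0.15) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = sprintf("Odds ratio (%g%% CI, log scale)", 100 * object$level),
                  y = NULL, title = df$rsid[1]) +
    ggplot2::theme_minimal()
}
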