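#' Bar chart of condition summaries with SEM error bars
#'
#' Mirrors the conventional presentation of interaction percentages:
#' grouped bars per gene pair and condition, error bars showing the SEM.
#'
#' @param summary Tibble from [summarize_condition()].
#' @return A ggplot object.
#' @export
plot_condition_summary <- function(summary) {
  ggplot2::ggplot(summary,
                  ggplot2::aes(x = .data$condition, y = .data$percent,
                               fill = .data$condition)) +
    ggplot2::geom_col(width = 0.7, show.legend = FALSE) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$percent - .data$sem,
                                        ymax = .data$percent + .data$sem),
                           width = 0.2) +
    ggplot2::facet_wrap(~gene_pair) +
    ggplot2::labs(x = NULL, y = "% interacting (≤ threshold)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.distance_histogram <- function(object, ...) {
  df <- tidy(object)
  df$mid <- ifelse(is.finite(df$bin_hi), (df$bin_lo + df$bin_hi) / 2,
                   df$bin_lo + 0.5)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mid, y = .data$count)) +
    ggplot2::geom_col(width = 0.9, fill = "grey35") +
    ggplot2::labs(x = "distance (µm)", y = "signal pairs") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.null_result <- function(object, ...) {
  autoplot(object$histogram) +
    ggplot2::geom_vline(xintercept = object$threshold_um, linetype = 2) +
    ggplot2::labs(subtitle = sprintf("%.2f%% of pairs within %g µm",
                                     100 * object$fraction_below_threshold,
                                     object$threshold_um))
}

#' Observed vs null distance distribution
#'
#' Side-by-side per-interval counts of an observed distance histogram and
#' the expectation under random placement.
#'
#' @param comparison A `null_comparison` from [compare_to_null()].
#' @return A ggplot object.
#' @export
plot_null_comparison <- function(comparison) {
  df <- tidy(comparison)
  df$mid <- ifelse(is.finite(df$bin_hi), (df$bin_lo + df$bin_hi) / 2,
                   df$bin_lo + 0.5)
  long <- tidyr::pivot_longer(df, c("observed", "expected"),
                              names_to = "source", values_to = "count")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$mid, y = .data$count,
                                     fill = .data$source)) +
    ggplot2::geom_col(position = "dodge", width = 0.85) +
    ggplot2::labs(x = "distance (µm)", y = "signal pairs", fill = NULL,
                  subtitle = sprintf("chi-squared p = %.3g", comparison$p_value)) +
    ggplot2::theme_minimal()
}
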