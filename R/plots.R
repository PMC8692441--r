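#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a log2 ratio profile along the Y MSY
#'
#' Line plot of per-window log2 coverage ratios (sample over young
#' reference) against position, with the zero line marking identical
#' coverage; sustained negative ratios indicate LOY, dips and spikes mark
#' structural heterogeneity.
#'
#' @param object A `ratio_profile` from [window_log2_profile()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @exportS3Method
autoplot.ratio_profile <- function(object, ...) {
  df <- as_tibble(object)
  df$mid <- (df$start + df$end) / 2 / 1e6
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mid, y = .data$log2_ratio)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::geom_line(colour = "firebrick") +
    ggplot2::labs(
      x = "Position on Y MSY (Mb)", y = "log2(sample / reference)",
      title = sprintf("%s vs %s  (median %.3f, variance %.4f)",
                      attr(object, "sample_id"),
                      attr(object, "reference_id"),
                      attr(object, "median_ratio"),
                      attr(object, "variance_ratio"))) +
    ggplot2::theme_minimal()
}

#' Boxplot of normalized dosage by chromosome
#'
#' The all-chromosome panel: per-chromosome distribution of
#' `diff = observed - expected` median coverage across samples. Under
#' pure Y loss only the Y box should sit below zero.
#'
#' @param estimates A `loy_estimate` tibble (rows from several samples).
#' @return A ggplot object.
#' @export
plot_chrom_dosage <- function(estimates) {
  require_columns(estimates, c("chrom", "diff", "class"), "estimate table")
  df <- as_tibble(estimates)
  df$chrom <- factor(df$chrom, levels = unique(df$chrom))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$chrom, y = .data$diff,
                                   fill = .data$class)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::labs(x = NULL, y = "Observed - expected median coverage",
                  fill = "Class") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60,
                                                       hjust = 1))
}

#' Boxplot of amplicon LOY scores by tissue and age group
#'
#' Per-tissue distribution of the log10 dosage score, split by age
#' group; 0 is dosage parity, negative is loss.
#'
#' @param scores Scored amplicon tibble from [amplicon_loy_score()] (or
#'   the `scores` element of an amplicon `screen_report`).
#' @return A ggplot object.
#' @export
plot_amplicon_scores <- function(scores) {
  require_columns(scores, c("tissue", "age_group", "score"), "score table")
  ggplot2::ggplot(as_tibble(scores),
                  ggplot2::aes(x = .data$tissue, y = .data$score,
                               fill = .data$age_group)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::labs(x = NULL, y = "log10 Y dosage score",
                  fill = "Age group") +
    ggplot2::theme_minimal()
}

#' Scatter of profile variance against median with trend lines
#'
#' The variance-median association plot: one point per sample, with the
#' all-points fit and (when available) the fit excluding the designated
#' anchor points.
#'
#' @param report A profile `screen_report` from [run_profile_analysis()].
#' @return A ggplot object.
#' @export
plot_variance_vs_median <- function(report) {
  df <- report$summary
  df$anchor <- df$sample_id %in% report$excluded
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$median_ratio,
                                        y = .data$variance_ratio)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$anchor), size = 2) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "black",
                                            `TRUE` = "dodgerblue")) +
    ggplot2::labs(x = "Median log2 ratio", y = "Variance of log2 ratios",
                  colour = "Anchor point") +
    ggplot2::theme_minimal()
  add_fit <- function(p, fit, colour) {
    if (is.null(fit)) return(p)
    p + ggplot2::geom_abline(slope = fit$slope, intercept = fit$intercept,
                             colour = colour)
  }
  p <- add_fit(p, report$fits$variance_vs_median_all, "grey60")
  add_fit(p, report$fits$variance_vs_median_excl, "black")
}
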