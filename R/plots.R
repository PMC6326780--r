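#' Plot per-position information content of a PWM
#' @param object An `itr_pwm`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.itr_pwm <- function(object, ...) {
  d <- tibble::tibble(position = seq_len(object$width), ic = object$ic)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$position, y = .data$ic)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "position", y = "information content (bits)") +
    ggplot2::theme_minimal()
}

#' Plot peak distance-tier fractions
#' @param assignments Output of [assign_peaks()].
#' @return A ggplot.
#' @export
plot_peak_tiers <- function(assignments) {
  s <- peak_tier_summary(assignments)
  s$tier <- factor(s$tier, levels = peak_tiers)
  ggplot2::ggplot(s, ggplot2::aes(x = .data$tier, y = .data$fraction)) +
    ggplot2::geom_col(fill = "darkorange") +
    ggplot2::labs(x = "distance tier to nearest ITR", y = "fraction of peaks") +
    ggplot2::theme_minimal()
}

#' Plot gene ChIP-class percentages
#' @param gene_classes Output of [classify_genes()].
#' @return A ggplot.
#' @export
plot_gene_classes <- function(gene_classes) {
  s <- gene_class_summary(gene_classes)
  ggplot2::ggplot(s, ggplot2::aes(x = .data$class, y = .data$pct)) +
    ggplot2::geom_col(fill = "seagreen") +
    ggplot2::labs(x = "gene class", y = "% of peak-bearing genes") +
    ggplot2::theme_minimal()
}

#' Smear plot of a differential-expression table
#'
#' Mean expression versus log2 fold-change, coloured by call.
#'
#' @param de Output of [apply_de_thresholds()] (needs `mean_expr`).
#' @return A ggplot.
#' @export
plot_de_smear <- function(de) {
  ggplot2::ggplot(de, ggplot2::aes(x = .data$mean_expr, y = .data$log2fc,
                                   colour = .data$call)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_colour_manual(values = c(up = "firebrick",
                                            down = "navy", ns = "grey70")) +
    ggplot2::labs(x = "mean expression", y = "log2 fold-change") +
    ggplot2::theme_minimal()
}
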