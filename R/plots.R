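# ggplot2 views of the main result types.

#' Boxplots of admixture scores by collection type
#'
#' @param object An `lmd_scores` tibble from [ssgsea_score()].
#' @param annotation Sample annotation tibble.
#' @param ... Unused.
#' @return A ggplot object: one panel per signature, scores by ET/ES/BT.
#' @exportS3Method ggplot2::autoplot
autoplot.lmd_scores <- function(object, annotation, ...) {
  dat <- dplyr::inner_join(object, annotation, by = "sample_id")
  ggplot2::ggplot(dat, ggplot2::aes(
    x = factor(.data$collection_type, levels = c("ET", "BT", "ES")),
    y = .data$score, fill = .data$collection_type)) +
    ggplot2::geom_boxplot(outlier.size = 0.6, show.legend = FALSE) +
    ggplot2::facet_wrap(~signature, scales = "free_y") +
    ggplot2::labs(x = "LMD collection type", y = "ssGSEA score") +
    ggplot2::theme_bw()
}

#' Volcano plot of a differential fit
#'
#' @param diff An `lmd_diff` from [moderated_ttest()].
#' @param alpha Adjusted-p significance cutoff to color by (default 0.05).
#' @return A ggplot object.
#' @export
plot_volcano <- function(diff, alpha = 0.05) {
  tab <- tidy(diff)
  tab$significant <- tab$adj_p < alpha
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$logfc,
                                    y = -log10(.data$p_value),
                                    color = .data$significant)) +
    ggplot2::geom_point(size = 0.7, alpha = 0.6) +
    ggplot2::scale_color_manual(values = c(`FALSE` = "grey60",
                                           `TRUE` = "firebrick")) +
    ggplot2::labs(x = "log2 fold change (ET vs ES)",
                  y = "-log10 p", color = sprintf("BH < %g", alpha)) +
    ggplot2::theme_bw()
}

#' Scatter of stroma score against true stroma fraction
#'
#' @param recovery Output of [purity_recovery()].
#' @return A ggplot object annotated with the Spearman rho.
#' @export
plot_purity_scatter <- function(recovery) {
  dat <- recovery$data
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$stroma_fraction,
                                    y = .data$score)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.4, color = "steelblue") +
    ggplot2::labs(
      x = "true stroma fraction (1 - tumor fraction)",
      y = "ssGSEA stroma score",
      subtitle = sprintf("Spearman rho = %.2f", recovery$rho)) +
    ggplot2::theme_bw()
}

#' Boxplots of within-group pairwise correlations
#'
#' @param pairs Output of [pairwise_spearman()].
#' @return A ggplot object: pairwise rho per patient, split by type.
#' @export
plot_pairwise_correlations <- function(pairs) {
  ggplot2::ggplot(pairs, ggplot2::aes(x = .data$patient, y = .data$rho,
                                      fill = .data$collection_type)) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::labs(x = "patient", y = "pairwise Spearman rho",
                  fill = "type") +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
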