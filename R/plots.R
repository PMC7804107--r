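# ggplot2 companions for the main result types. These are convenience
# views; no analysis contract attaches to them.

#' Volcano plot of a differential-expression result
#'
#' @param object A [differential_expression()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot de_result
#' @export
autoplot.de_result <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = log2(.data$fold_change),
                               y = -log10(pmax(.data$fdr, 1e-300)),
                               colour = .data$direction)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::scale_colour_manual(values = c(up = "#c0392b", down = "#2980b9",
                                            ns = "grey70")) +
    ggplot2::labs(x = "log2 fold change", y = "-log10 FDR",
                  colour = NULL,
                  title = sprintf("%s vs %s", attr(object, "test_condition"),
                                  attr(object, "ref_condition"))) +
    ggplot2::theme_minimal()
}

#' Heatmap of a masked correlation or odds-ratio matrix
#'
#' @param object A `masked_correlation` or `odds_ratio_result`.
#' @param ... Unused.
#' @return A ggplot object (tile heatmap of the masked matrix).
#' @method autoplot masked_correlation
#' @export
autoplot.masked_correlation <- function(object, ...) {
  plot_masked_matrix(object$rho_masked, "Spearman rho (masked)")
}

#' @rdname autoplot.masked_correlation
#' @method autoplot odds_ratio_result
#' @export
autoplot.odds_ratio_result <- function(object, ...) {
  plot_masked_matrix(object$log2_or_masked, "log2 odds ratio (masked)")
}

plot_masked_matrix <- function(m, legend) {
  df <- as_tibble(as.table(m), .name_repair = ~ c("feature_i", "feature_j", "value"))
  df$feature_i <- factor(df$feature_i, levels = rownames(m))
  df$feature_j <- factor(df$feature_j, levels = colnames(m))
  ggplot2::ggplot(df, ggplot2::aes(.data$feature_i, .data$feature_j,
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", midpoint = 0) +
    ggplot2::labs(x = NULL, y = NULL, fill = legend) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, hjust = 1))
}

#' Noise-shift plot: single-stimulus vs co-stimulated Fano factors
#'
#' @param noise A [fano_table()] result computed with program sets.
#' @param program A `program_sets` with cross-regulation labels (used to
#'   colour inhibited vs augmented genes); optional.
#' @return A ggplot object.
#' @export
plot_noise_shift <- function(noise, program = NULL) {
  stopifnot(inherits(noise, "noise_table"))
  if (is.null(noise$delta)) abort("Fano table lacks the UCG delta; rerun with `program`.")
  d <- noise$delta
  if (!is.null(program) && nrow(program$cross_regulation)) {
    d <- left_join(d, program$cross_regulation[, c("gene", "label")],
                   by = "gene")
  } else {
    d$label <- "ucg"
  }
  ggplot2::ggplot(d, ggplot2::aes(.data$fano_single, .data$fano_costim,
                                  colour = .data$label)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::facet_wrap(~ program) +
    ggplot2::labs(x = "Fano factor, single stimulus",
                  y = "Fano factor, co-stimulation", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Scatter of paired UCG scores for co-stimulated cells
#'
#' @param scores A [ucg_score_pair()] tibble.
#' @return A ggplot object.
#' @export
plot_ucg_scores <- function(scores) {
  ggplot2::ggplot(scores, ggplot2::aes(.data$score_A, .data$score_B)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::labs(x = "program A score", y = "program B score") +
    ggplot2::theme_minimal()
}

#' Bar chart comparing dominance-label counts across feature sets
#'
#' @param comparison A [compare_feature_sets()] result.
#' @return A ggplot object.
#' @export
plot_dominance_comparison <- function(comparison) {
  long <- tidyr::pivot_longer(comparison, cols = dplyr::starts_with("n_"),
                              names_to = "feature_set", values_to = "n")
  long$feature_set <- sub("^n_", "", long$feature_set)
  ggplot2::ggplot(long, ggplot2::aes(.data$label, .data$n,
                                     fill = .data$feature_set)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "cells", fill = "features") +
    ggplot2::theme_minimal()
}

#' Heatmap of consensus-cluster secretion profiles
#'
#' @param clustering A [consensus_cluster()] result.
#' @return A ggplot object.
#' @export
plot_cluster_profiles <- function(clustering) {
  prof <- cluster_profiles(clustering)
  long <- tidyr::pivot_longer(prof, cols = -c("cluster", "n_wells", "fraction"),
                              names_to = "analyte", values_to = "mean_transformed")
  ggplot2::ggplot(long, ggplot2::aes(.data$analyte, factor(.data$cluster),
                                     fill = .data$mean_transformed)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "#b2182b") +
    ggplot2::labs(x = NULL, y = "consensus cluster", fill = "mean asinh") +
    ggplot2::theme_minimal()
}
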