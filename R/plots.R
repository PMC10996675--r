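#' Heatmap of the lipid-by-protein correlation matrix
#'
#' Tiles tau values with axes in dendrogram order when cluster models are
#' supplied, the standard fingerprint view of a cross-ome run.
#'
#' @param cm Long cross-correlation tibble.
#' @param protein_clusters,lipid_clusters Optional `crossome_clusters`
#'   models supplying the axis orderings.
#' @return A ggplot object.
#' @export
plot_crossome <- function(cm, protein_clusters = NULL, lipid_clusters = NULL) {
  dat <- cm
  if (!is.null(lipid_clusters)) {
    dat$lipid_id <- factor(dat$lipid_id,
                           levels = lipid_clusters$dendrogram_order)
  }
  if (!is.null(protein_clusters)) {
    dat$protein_id <- factor(dat$protein_id,
                             levels = protein_clusters$dendrogram_order)
  }
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$protein_id, y = .data$lipid_id,
                                    fill = .data$tau)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "white",
                                  high = "#B2182B", limits = c(-1, 1),
                                  na.value = "grey90") +
    ggplot2::labs(x = "protein", y = "lipid", fill = "Kendall tau-b") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank(),
                   panel.grid = ggplot2::element_blank())
}

#' Per-genotype signature profiles
#'
#' @param signatures Signature tibble from [cluster_signatures()] or
#'   [module_signatures()].
#' @return A ggplot heatmap of aggregated log2 fold change per (set,
#'   genotype).
#' @export
plot_signatures <- function(signatures) {
  ggplot2::ggplot(signatures,
                  ggplot2::aes(x = .data$genotype, y = .data$set_id,
                               fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "white",
                                  high = "#B2182B", na.value = "grey90") +
    ggplot2::labs(x = NULL, y = NULL,
                  fill = expression(log[2] * "FC (KO/control)")) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5,
                                                       hjust = 1))
}

#' Chain-length partition bar chart
#'
#' @param profile Tibble from [chain_length_profile()].
#' @return A ggplot object comparing the short- and long-chain group means.
#' @export
plot_chain_length <- function(profile) {
  ggplot2::ggplot(profile,
                  ggplot2::aes(x = .data$group, y = .data$mean_log2fc)) +
    ggplot2::geom_col(fill = "#4393C3") +
    ggplot2::geom_text(ggplot2::aes(label = paste0("n=", .data$n_members)),
                       vjust = -0.4, size = 3) +
    ggplot2::labs(x = "total carbons vs cutoff",
                  y = expression("mean " * log[2] * "FC")) +
    ggplot2::theme_minimal()
}

#' @describeIn cluster_axis Autoplot method: cluster sizes per axis.
#' @param object A `crossome_clusters` object.
#' @param ... Unused.
#' @export
autoplot.crossome_clusters <- function(object, ...) {
  sizes <- dplyr::count(object$assignments, .data$cluster)
  ggplot2::ggplot(sizes, ggplot2::aes(x = factor(.data$cluster),
                                      y = .data$n)) +
    ggplot2::geom_col(fill = "#4393C3") +
    ggplot2::labs(x = sprintf("%s cluster (k = %d)", object$axis, object$k),
                  y = "members") +
    ggplot2::theme_minimal()
}

#' @describeIn outlier_analysis Autoplot method: robust z per genotype with
#'   the flag cutoff.
#' @param object A `crossome_outliers` object.
#' @param ... Unused.
#' @export
autoplot.crossome_outliers <- function(object, ...) {
  ggplot2::ggplot(object$scores,
                  ggplot2::aes(x = .data$genotype, y = .data$robust_z,
                               colour = .data$flagged)) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.6, size = 0.8) +
    ggplot2::geom_hline(yintercept = c(-1, 1) * object$z_cutoff,
                        linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "#B2182B")) +
    ggplot2::labs(x = NULL, y = "robust z", colour = "flagged") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5,
                                                       hjust = 1))
}
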