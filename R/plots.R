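#' Heatmap of group-level median correlations
#'
#' The origin x target analogue of the study heatmaps: each cell is the
#' median, over model samples of one origin tissue and model type, of the
#' per-model median correlation to a target tissue group.
#'
#' @param object A `specificity_summary`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.specificity_summary <- function(object, ...) {
  df <- dplyr::mutate(
    object$group_medians,
    target = paste(.data$tissue_group, .data$disease_state, sep = "\n"),
    origin = paste(.data$model_tissue_group, .data$model_type, sep = "\n")
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$target, .data$origin,
                                   fill = .data$median_rho)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$median_rho)),
                       size = 3) +
    ggplot2::scale_fill_viridis_c(limits = c(-1, 1), name = "median rho") +
    ggplot2::labs(
      x = "target tissue group", y = "model origin",
      title = sprintf("Model-tissue correlation (gene subset: %s)",
                      object$gene_subset)
    ) +
    ggplot2::theme_minimal()
}

#' Distribution of per-model matched-origin correlations
#'
#' Violin plots of the per-model-sample median correlation to each tissue
#' group, split by model type — the cell-line vs PDX comparison view.
#'
#' @param records Correlation records from [model_to_tissue()].
#' @return A ggplot object.
#' @export
plot_correlation_distributions <- function(records) {
  df <- dplyr::mutate(
    records, target = paste(.data$tissue_group, .data$disease_state,
                            sep = "\n")
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$target, .data$rho_median,
                                   fill = .data$model_type)) +
    ggplot2::geom_violin(position = ggplot2::position_dodge(width = 0.8),
                         alpha = 0.7) +
    ggplot2::labs(x = "tissue group", y = "median Spearman rho",
                  fill = "model type") +
    ggplot2::theme_minimal()
}

#' PCA QC scatter plot
#'
#' @param object A `pca_qc` result.
#' @param colour Metadata column (string) used for point colour, if the
#'   scores carry metadata.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.pca_qc <- function(object, colour = "model_type", ...) {
  vf <- object$variance$variance_fraction
  p <- ggplot2::ggplot(object$scores, ggplot2::aes(.data$PC1, .data$PC2))
  if (colour %in% names(object$scores)) {
    p <- p + ggplot2::geom_point(ggplot2::aes(colour = .data[[colour]]))
  } else {
    p <- p + ggplot2::geom_point()
  }
  p +
    ggplot2::labs(
      x = sprintf("PC1 (%.0f%% of variance)", 100 * vf[1]),
      y = sprintf("PC2 (%.0f%% of variance)", 100 * vf[2])
    ) +
    ggplot2::theme_minimal()
}

#' Histogram of per-gene correlation classes
#'
#' The per-gene rho distribution coloured by significance class, the
#' classification view of a model-group vs tissue-group comparison.
#'
#' @param records Tibble from [per_gene_correlation()].
#' @return A ggplot object.
#' @export
plot_gene_correlation <- function(records) {
  df <- dplyr::filter(records, !is.na(.data$rho))
  ggplot2::ggplot(df, ggplot2::aes(.data$rho, fill = .data$class)) +
    ggplot2::geom_histogram(bins = 50, boundary = 0) +
    ggplot2::labs(x = "Spearman rho (quantile-paired)", y = "genes",
                  fill = "class") +
    ggplot2::theme_minimal()
}
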