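#' Heatmap of a contact matrix
#'
#' @param m contact matrix (observed, improved, or a mega matrix).
#' @param log_scale color on `log1p` counts (default `TRUE`).
#' @param title optional plot title.
#' @return a ggplot object.
#' @export
plot_contact_matrix <- function(m, log_scale = TRUE, title = NULL) {
  mm <- unclass(as.matrix(m))
  df <- tidyr::expand_grid(i = seq_len(nrow(mm)), j = seq_len(ncol(mm)))
  df$count <- mm[cbind(df$i, df$j)]
  if (log_scale) df$count <- log1p(df$count)
  ggplot2::ggplot(df, ggplot2::aes(.data$j, .data$i, fill = .data$count)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(
      name = if (log_scale) "log1p(count)" else "count"
    ) +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = title, x = "bin", y = "bin") +
    ggplot2::theme_minimal()
}

#' ROC curve plot
#'
#' @param object a `schic_roc` from [roc_auc()] or a named list of them.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot schic_roc
#' @export
autoplot.schic_roc <- function(object, ...) {
  plot_roc(list(model = object))
}

#' @rdname autoplot.schic_roc
#' @param rocs named list of `schic_roc` objects to overlay.
#' @export
plot_roc <- function(rocs) {
  df <- purrr::map_dfr(names(rocs), function(nm) {
    dplyr::mutate(rocs[[nm]]$roc,
      method = sprintf("%s (AUC %.2f)", nm, rocs[[nm]]$auc)
    )
  })
  ggplot2::ggplot(df, ggplot2::aes(.data$fpr, .data$sensitivity,
    color = .data$method
  )) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 3, color = "grey60") +
    ggplot2::geom_step() +
    ggplot2::labs(
      x = "1 - PTDO (false structural-zero rate)",
      y = "PTSZ (sensitivity)", color = NULL
    ) +
    ggplot2::theme_minimal()
}

#' Expected/observed-versus-imputed scatter (SEVI / SOVI)
#'
#' @param data tibble from [sevi_data()].
#' @param xlab axis label for the reference values.
#' @return a ggplot object; observed zeros are drawn in red.
#' @export
plot_sevi <- function(data, xlab = "expected") {
  ggplot2::ggplot(data, ggplot2::aes(.data$reference, .data$imputed,
    color = .data$observed_zero
  )) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 3) +
    ggplot2::scale_color_manual(
      values = c(`FALSE` = "grey30", `TRUE` = "red"),
      name = "observed zero"
    ) +
    ggplot2::labs(x = xlab, y = "imputed") +
    ggplot2::theme_minimal()
}

#' Embedding / elbow plots for a clustering result
#'
#' @param object a `schic_embedding` from [embed_and_kmeans()].
#' @param which `"embedding"` (cells in 2D, colored by cluster) or
#'   `"elbow"` (within-cluster sum of squares by k).
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot schic_embedding
#' @export
autoplot.schic_embedding <- function(object, which = c("embedding", "elbow"),
                                     ...) {
  which <- match.arg(which)
  if (which == "embedding") {
    ggplot2::ggplot(object$cells, ggplot2::aes(.data$dim1, .data$dim2,
      color = factor(.data$cluster)
    )) +
      ggplot2::geom_point(size = 2) +
      ggplot2::labs(
        x = if (object$use_tsne) "t-SNE 1" else "PC 1",
        y = if (object$use_tsne) "t-SNE 2" else "PC 2",
        color = "cluster"
      ) +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(object$wss_by_k, ggplot2::aes(.data$k, .data$wss)) +
      ggplot2::geom_line() +
      ggplot2::geom_point() +
      ggplot2::labs(x = "number of clusters k", y = "total within-cluster SS") +
      ggplot2::theme_minimal()
  }
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Two-way heatmap of top-variance positions
#'
#' Positions-by-cells heatmap of the highest-variance upper-triangle
#' positions, with rows and columns ordered by complete-linkage hierarchical
#' clustering — the display used to inspect candidate subtypes.
#'
#' @param top result of [top_variable_positions()].
#' @param cell_labels optional labels for the cell axis.
#' @return a ggplot object.
#' @export
plot_position_heatmap <- function(top, cell_labels = NULL) {
  sub <- top$submatrix
  ro <- stats::hclust(stats::dist(sub), method = "complete")$order
  co <- stats::hclust(stats::dist(t(sub)), method = "complete")$order
  if (is.null(cell_labels)) cell_labels <- as.character(seq_len(ncol(sub)))
  df <- tidyr::expand_grid(
    position = seq_len(nrow(sub)),
    cell = seq_len(ncol(sub))
  )
  df$value <- sub[cbind(df$position, df$cell)]
  df$position <- factor(df$position, levels = ro)
  df$cell <- factor(cell_labels[df$cell], levels = cell_labels[co])
  ggplot2::ggplot(df, ggplot2::aes(.data$cell, .data$position,
    fill = .data$value
  )) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "value") +
    ggplot2::labs(x = "cell", y = "position") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}
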