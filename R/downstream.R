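#' Per-cell feature vectors for clustering
#'
#' Optionally rescales each cell to a common total count (the maximum cell
#' total), applies `log(1 + x)`, and flattens the strict upper triangle into
#' one feature vector per cell.
#'
#' @param cells list of contact matrices (observed or improved).
#' @param log_transform apply `log1p` (default `TRUE`).
#' @param depth_normalize rescale cells to a common total first (default
#'   `TRUE`).
#' @return `K x n(n-1)/2` feature matrix, one row per cell.
#' @export
cluster_features <- function(cells, log_transform = TRUE,
                             depth_normalize = TRUE) {
  feats <- t(vapply(
    cells,
    function(m) vectorize_upper(unclass(as.matrix(m))),
    numeric(nrow(as.matrix(cells[[1]])) * (nrow(as.matrix(cells[[1]])) - 1) / 2)
  ))
  if (depth_normalize) {
    tot <- rowSums(feats)
    target <- max(tot)
    feats <- feats * target / ifelse(tot == 0, 1, tot)
  }
  if (log_transform) feats <- log1p(feats)
  rownames(feats) <- if (!is.null(names(cells))) names(cells)
  feats
}

#' Embed cells and cluster with K-means
#'
#' Optionally embeds the feature vectors in 2D with t-SNE (perplexity
#' `min(30, (K - 1) / 3)` unless given), then runs K-means with multiple
#' restarts either on the embedding (figure-style) or on the raw features.
#' The within-cluster sum of squares is reported for `k = 1..k_max` for
#' elbow inspection.
#'
#' @param features `K x P` matrix from [cluster_features()].
#' @param k number of clusters.
#' @param seed integer seed controlling both t-SNE and K-means.
#' @param use_tsne embed with t-SNE before clustering (default `TRUE`).
#' @param k_max largest k for the elbow curve (default `min(6, K - 1)`).
#' @param perplexity t-SNE perplexity; default `min(30, (K - 1) / 3)`.
#' @param nstart K-means restarts (default 25).
#' @param reference optional reference labels; adds their ARI.
#' @return object of class `schic_embedding`: tibble `cells` (`cell`,
#'   `dim1`, `dim2`, `cluster`), tibble `wss_by_k`, scalar `ari` (or `NA`).
#' @export
embed_and_kmeans <- function(features, k, seed = 1, use_tsne = TRUE,
                             k_max = NULL, perplexity = NULL, nstart = 25,
                             reference = NULL) {
  K <- nrow(features)
  if (k > K) stop("k = ", k, " exceeds the number of cells (", K, ")")
  if (is.null(k_max)) k_max <- max(k, min(6, K - 1))
  set.seed(seed)
  if (use_tsne) {
    if (is.null(perplexity)) perplexity <- max(0.5, min(30, (K - 1) / 3))
    emb <- Rtsne::Rtsne(features,
      dims = 2, perplexity = perplexity,
      check_duplicates = FALSE, pca = K > 30, max_iter = 500
    )$Y
    space <- emb
  } else {
    pc <- stats::prcomp(features, rank. = 2)
    emb <- pc$x[, 1:2, drop = FALSE]
    space <- features
  }
  km <- stats::kmeans(space, centers = k, nstart = nstart)
  wss <- vapply(seq_len(k_max), function(kk) {
    if (kk == 1) {
      sum(scale(space, scale = FALSE)^2)
    } else {
      stats::kmeans(space, centers = kk, nstart = nstart)$tot.withinss
    }
  }, numeric(1))
  ari_val <- if (!is.null(reference)) ari(km$cluster, reference) else NA_real_
  structure(
    list(
      cells = tibble::tibble(
        cell = if (!is.null(rownames(features))) {
          rownames(features)
        } else {
          as.character(seq_len(K))
        },
        dim1 = emb[, 1], dim2 = emb[, 2],
        cluster = km$cluster
      ),
      wss_by_k = tibble::tibble(k = seq_len(k_max), wss = wss),
      ari = ari_val, k = k, use_tsne = use_tsne, seed = seed
    ),
    class = "schic_embedding"
  )
}

#' @export
print.schic_embedding <- function(x, ...) {
  cat("<schic_embedding> ", nrow(x$cells), " cells, k = ", x$k,
    if (x$use_tsne) ", t-SNE" else ", feature space",
    if (!is.na(x$ari)) paste0(", ARI = ", format(x$ari, digits = 3)), "\n",
    sep = ""
  )
  invisible(x)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected pair-counting agreement between two labelings of the
#' same cells; 1 for identical partitions (up to label permutation), about 0
#' for independent ones.
#'
#' @param labels_a,labels_b equal-length label vectors.
#' @return scalar ARI.
#' @export
ari <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b)) stop("label length mismatch")
  ct <- table(labels_a, labels_b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(ct))
  sum_a <- sum(comb2(rowSums(ct)))
  sum_b <- sum(comb2(colSums(ct)))
  n2 <- comb2(length(labels_a))
  expected <- sum_a * sum_b / n2
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) {
    return(ifelse(sum_ij == expected, 1, 0))
  }
  (sum_ij - expected) / (max_idx - expected)
}

#' Positions with the highest across-cell variance
#'
#' Ranks upper-triangle positions by variance across cells and returns the
#' top set together with the positions-by-cells submatrix used for two-way
#' heatmaps.
#'
#' @param features `K x P` feature matrix.
#' @param n_top number of positions to keep (default 500).
#' @return list: `idx` (column indices, decreasing variance), `pairs`
#'   (tibble with `i`, `j`, `variance`), `submatrix`
#'   (`n_top x K`, positions by cells).
#' @export
top_variable_positions <- function(features, n_top = 500) {
  P <- ncol(features)
  if (n_top > P) stop("n_top exceeds the number of positions (", P, ")")
  v <- apply(features, 2, stats::var)
  idx <- order(v, decreasing = TRUE)[seq_len(n_top)]
  n <- (1 + sqrt(1 + 8 * P)) / 2
  pairs <- upper_pairs(n)[idx, ]
  pairs$variance <- v[idx]
  list(idx = idx, pairs = pairs, submatrix = t(features[, idx, drop = FALSE]))
}

#' Mega matrix of a cell cluster
#'
#' Entry-wise sum of all cells in a cluster, rescaled to a common total
#' count and min-max scaled to `[0, 1]` for visual comparison between
#' clusters.
#'
#' @param cells non-empty list of matrices in one cluster.
#' @param common_total total count to normalize to before min-max scaling
#'   (default: the summed matrix's own total, i.e. no renormalization).
#' @return matrix with entries in `[0, 1]` (max exactly 1 for nonzero
#'   input).
#' @export
mega_matrix <- function(cells, common_total = NULL) {
  if (length(cells) == 0) stop("empty cluster")
  s <- Reduce(`+`, lapply(cells, function(m) unclass(as.matrix(m))))
  tot <- sum(s)
  if (!is.null(common_total) && tot > 0) s <- s * common_total / tot
  rng <- range(s)
  if (rng[2] == rng[1]) {
    return(matrix(0, nrow(s), ncol(s)))
  }
  (s - rng[1]) / (rng[2] - rng[1])
}

#' Mega matrices for every cluster
#'
#' @param cells list of matrices.
#' @param labels cluster label per cell.
#' @return named list of [mega_matrix()] results, all normalized to the same
#'   total before scaling.
#' @export
mega_matrices <- function(cells, labels) {
  if (length(cells) != length(labels)) stop("labels length mismatch")
  split_idx <- split(seq_along(cells), labels)
  totals <- vapply(split_idx, function(ix) {
    sum(Reduce(`+`, lapply(cells[ix], function(m) unclass(as.matrix(m)))))
  }, numeric(1))
  common <- min(totals[totals > 0])
  lapply(split_idx, function(ix) mega_matrix(cells[ix], common_total = common))
}

#' Hierarchical clustering dendrogram of cells
#'
#' Complete-linkage agglomerative clustering on Euclidean distances between
#' feature vectors; exportable to newick.
#'
#' @param features `K x P` feature matrix (row names label the leaves).
#' @param linkage linkage method (default `"complete"`).
#' @return an [stats::hclust] tree.
#' @export
hclust_dendrogram <- function(features, linkage = "complete") {
  if (nrow(features) < 2) stop("need at least 2 cells")
  stats::hclust(stats::dist(features), method = linkage)
}

#' Write a dendrogram as a newick file
#'
#' @param hc an [stats::hclust] tree.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
export_newick <- function(hc, path) {
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}
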