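#' Bundle single-cell contact matrices (and optional bulk) into a group
#'
#' A `schic_group` holds the K single-cell contact matrices that are modelled
#' together, an optional bulk matrix on the same bins, the per-cell depths
#' \eqn{T_k} (strict upper-triangle sums), the normalization target depth
#' \eqn{T}, and the proportionate depths \eqn{\lambda^k = T_k / T}. By default
#' \eqn{T} is the maximum depth over the cells, so \eqn{0 < \lambda^k \le 1};
#' alternatively a fixed target (e.g. 300000, roughly the depth of the best
#' available K562 single cells) can be supplied.
#'
#' @param cells list of contact matrices (or plain symmetric count matrices),
#'   all of one dimension.
#' @param bulk optional bulk contact matrix on the same bins.
#' @param target_depth optional fixed normalization depth \eqn{T}; default is
#'   `max(T_k)`.
#' @param labels optional cell labels; defaults to `cell01, cell02, ...` or
#'   the matrices' own labels.
#'
#' @return object of class `schic_group`: a list with elements `cells`,
#'   `bulk`, `depths`, `target_depth`, `lambdas`, `n_bins`, `labels`.
#' @export
#' @examples
#' a <- contact_matrix(rbind(c(0, 2), c(2, 0)))
#' b <- contact_matrix(rbind(c(0, 4), c(4, 0)))
#' g <- schic_group(list(a, b))
#' g$lambdas # 0.5, 1
schic_group <- function(cells, bulk = NULL, target_depth = NULL,
                        labels = NULL) {
  if (length(cells) == 0) stop("empty group: no cells supplied")
  cells <- lapply(cells, function(m) {
    if (inherits(m, "contact_matrix")) m else contact_matrix(m)
  })
  n <- nrow(cells[[1]])
  dims <- vapply(cells, nrow, integer(1))
  if (any(dims != n)) {
    stop("cell matrices differ in dimension: ", paste(unique(dims), collapse = ", "))
  }
  if (!is.null(bulk)) {
    if (!inherits(bulk, "contact_matrix")) bulk <- contact_matrix(bulk)
    if (nrow(bulk) != n) {
      stop("bulk dimension ", nrow(bulk), " does not match cells (", n, ")")
    }
  }
  if (is.null(labels)) {
    labels <- vapply(seq_along(cells), function(k) {
      lb <- attr(cells[[k]], "label")
      if (is.null(lb)) sprintf("cell%02d", k) else lb
    }, character(1))
  }
  depths <- vapply(cells, matrix_depth, numeric(1))
  target <- if (is.null(target_depth)) max(depths) else target_depth
  if (target <= 0) stop("target depth must be positive")
  structure(
    list(
      cells = cells, bulk = bulk, depths = depths,
      target_depth = target, lambdas = depths / target,
      n_bins = n, labels = labels
    ),
    class = "schic_group"
  )
}

#' @export
print.schic_group <- function(x, ...) {
  cat("<schic_group> ", length(x$cells), " cells, ", x$n_bins, " bins",
    if (!is.null(x$bulk)) ", with bulk" else ", no bulk", "\n",
    sep = ""
  )
  cat(
    "  depths T_k: ", paste(format(x$depths), collapse = " "),
    "\n  target T = ", format(x$target_depth), "\n",
    sep = ""
  )
  invisible(x)
}

#' Load a group of single-cell matrices from files
#'
#' @param cell_paths character vector of per-cell files (triplet or dense,
#'   see [read_contact_matrix()]).
#' @param bulk_path optional bulk matrix file.
#' @param target_depth optional normalization depth \eqn{T} (default:
#'   maximum cell depth).
#' @param format,n passed to [read_contact_matrix()].
#' @return a [schic_group()].
#' @export
group_from_files <- function(cell_paths, bulk_path = NULL,
                             target_depth = NULL, format = "auto", n = NULL) {
  if (length(cell_paths) == 0) stop("empty group: no cell files")
  cells <- lapply(cell_paths, read_contact_matrix, format = format, n = n)
  bulk <- if (!is.null(bulk_path)) {
    read_contact_matrix(bulk_path, format = format, n = n)
  }
  schic_group(cells, bulk = bulk, target_depth = target_depth,
    labels = sub("\\.[^.]*$", "", basename(cell_paths)))
}

#' Depth summary of a group as a tibble
#'
#' @param x a `schic_group`.
#' @param ... unused.
#' @return tibble with one row per cell: `cell`, `depth`, `lambda`,
#'   `sparsity` (fraction of zero upper-triangle entries).
#' @method tidy schic_group
#' @export
tidy.schic_group <- function(x, ...) {
  tibble::tibble(
    cell = x$labels,
    depth = x$depths,
    lambda = x$lambdas,
    sparsity = vapply(
      x$cells,
      function(m) mean(vectorize_upper(m) == 0), numeric(1)
    )
  )
}
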