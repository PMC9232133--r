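#' Construct a contact matrix
#'
#' A contact matrix is a square, symmetric, nonnegative matrix of interaction
#' frequencies between pairs of genomic bins. On ingestion entries must be
#' integral; imputed (improved) matrices relax integrality but stay
#' nonnegative.
#'
#' @param counts square numeric matrix of interaction counts.
#' @param bin_size optional bin width in base pairs (metadata).
#' @param chrom optional chromosome name (metadata).
#' @param label optional cell/sample identifier.
#' @param integral require integer-valued entries (default `TRUE`).
#'
#' @return a matrix of class `contact_matrix` with metadata attributes.
#' @export
#' @examples
#' m <- contact_matrix(rbind(c(0, 4), c(4, 0)))
#' matrix_depth(m)
contact_matrix <- function(counts, bin_size = NULL, chrom = NULL,
                           label = NULL, integral = TRUE) {
  counts <- as.matrix(counts)
  if (nrow(counts) != ncol(counts)) {
    stop("contact matrix must be square, got ", nrow(counts), "x", ncol(counts))
  }
  if (anyNA(counts)) stop("contact matrix contains missing values")
  if (any(counts < 0)) stop("contact matrix contains negative counts")
  if (!isSymmetric(unname(counts), tol = 1e-8)) {
    stop("contact matrix must be symmetric")
  }
  if (integral && any(abs(counts - round(counts)) > 1e-8)) {
    stop("counts must be integral on ingestion")
  }
  dimnames(counts) <- NULL
  structure(counts,
    bin_size = bin_size, chrom = chrom, label = label,
    class = c("contact_matrix", class(counts))
  )
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat(
    "<contact_matrix> ", nrow(x), "x", ncol(x),
    if (!is.null(attr(x, "label"))) paste0(" [", attr(x, "label"), "]"),
    "  depth (upper-tri sum) = ", format(matrix_depth(x)), "\n",
    sep = ""
  )
  invisible(x)
}

#' Sequencing depth of a contact matrix
#'
#' The depth of a cell is the sum of its strict upper triangle
#' \eqn{T_k = \sum_{i<j} Y_{ijk}}; diagonal entries are excluded throughout,
#' since the model only considers pairs of distinct loci.
#'
#' @param m contact matrix (or plain symmetric matrix).
#' @return scalar total count over pairs `i < j`.
#' @export
matrix_depth <- function(m) {
  sum(m[upper.tri(m)])
}

#' Read a contact matrix from a text file
#'
#' Two plain-text formats are supported: `"triplet"` — tab/space-delimited
#' rows `i j count` with 0-based bin indices, each unordered pair stored once
#' (conventionally `i <= j`); and `"dense"` — whitespace-delimited `n` rows of
#' `n` numbers. Triplet entries are mirrored to both `(i, j)` and `(j, i)`;
#' duplicate triplets for one unordered pair are summed.
#'
#' @param path file path.
#' @param format `"auto"` (guess from the first line), `"triplet"` or
#'   `"dense"`.
#' @param n bin count, required for triplet files unless inferable as
#'   `max(index) + 1`.
#' @param integral require integral entries (see [contact_matrix()]).
#' @param ... metadata passed to [contact_matrix()].
#' @return a `contact_matrix`.
#' @export
read_contact_matrix <- function(path, format = c("auto", "triplet", "dense"),
                                n = NULL, integral = TRUE, ...) {
  format <- match.arg(format)
  tab <- utils::read.table(path, header = FALSE)
  if (format == "auto") {
    format <- if (ncol(tab) == 3 && nrow(tab) != 3) "triplet" else "dense"
    # a 3x3 dense matrix is ambiguous; triplet indices must be integral
    if (ncol(tab) == 3 && nrow(tab) == 3) {
      idx <- as.matrix(tab[, 1:2])
      format <- if (all(idx == round(idx)) && max(idx) <= 2 && min(idx) >= 0 &&
        !isSymmetric(unname(as.matrix(tab)))) "triplet" else "dense"
    }
  }
  if (format == "triplet") {
    if (ncol(tab) != 3) stop("triplet file must have 3 columns, got ", ncol(tab))
    i <- tab[[1]]; j <- tab[[2]]; cnt <- tab[[3]]
    if (any(i != round(i)) || any(j != round(j))) stop("triplet indices must be integers")
    if (any(cnt < 0)) stop("negative counts in ", path)
    if (is.null(n)) n <- max(i, j) + 1L
    if (any(i < 0 | j < 0 | i >= n | j >= n)) {
      stop("triplet index out of range for n = ", n)
    }
    counts <- matrix(0, n, n)
    for (r in seq_along(i)) {
      counts[i[r] + 1L, j[r] + 1L] <- counts[i[r] + 1L, j[r] + 1L] + cnt[r]
      if (i[r] != j[r]) {
        counts[j[r] + 1L, i[r] + 1L] <- counts[j[r] + 1L, i[r] + 1L] + cnt[r]
      }
    }
  } else {
    counts <- as.matrix(tab)
    if (nrow(counts) != ncol(counts)) {
      stop("dense file is not square: ", nrow(counts), "x", ncol(counts))
    }
    if (!is.null(n) && nrow(counts) != n) {
      stop("dense file has ", nrow(counts), " bins, expected ", n)
    }
  }
  contact_matrix(counts, integral = integral, ...)
}

#' Write a contact matrix to a text file
#'
#' @inheritParams read_contact_matrix
#' @param m matrix to write.
#' @param format `"triplet"` writes each unordered pair with a nonzero count
#'   once (`i <= j`, 0-based, tab-delimited); `"dense"` writes the full
#'   matrix.
#' @return `path`, invisibly.
#' @export
write_contact_matrix <- function(m, path, format = c("triplet", "dense")) {
  format <- match.arg(format)
  if (format == "triplet") {
    keep <- which(upper.tri(m, diag = TRUE) & m != 0, arr.ind = TRUE)
    df <- data.frame(i = keep[, 1] - 1L, j = keep[, 2] - 1L, count = m[keep])
    df <- df[order(df$i, df$j), ]
    utils::write.table(df, path,
      sep = "\t", quote = FALSE,
      row.names = FALSE, col.names = FALSE
    )
  } else {
    utils::write.table(as.matrix(unclass(m)), path,
      sep = "\t", quote = FALSE,
      row.names = FALSE, col.names = FALSE
    )
  }
  invisible(path)
}

#' Upper-triangle vectorization
#'
#' Flattens the strict upper triangle of a symmetric matrix into a vector of
#' length `n(n-1)/2` in fixed row-major order (`(1,2), (1,3), ..., (1,n),
#' (2,3), ...`), the pair order used everywhere in the package.
#'
#' @param m symmetric matrix.
#' @return numeric vector of length `n(n-1)/2` with attribute `n`.
#' @seealso [devectorize_upper()], [upper_pairs()]
#' @export
vectorize_upper <- function(m) {
  n <- nrow(m)
  v <- t(m)[lower.tri(m)] # row-major strict upper triangle
  attr(v, "n") <- n
  v
}

#' Rebuild a symmetric matrix from its upper-triangle vector
#'
#' @param v vector produced by [vectorize_upper()] (or any vector of length
#'   `n(n-1)/2`).
#' @param n matrix dimension; taken from `attr(v, "n")` when absent.
#' @param diag value(s) for the diagonal (default 0).
#' @return symmetric `n x n` matrix.
#' @export
devectorize_upper <- function(v, n = attr(v, "n"), diag = 0) {
  if (is.null(n)) {
    n <- (1 + sqrt(1 + 8 * length(v))) / 2
    if (n != round(n)) stop("length ", length(v), " is not n(n-1)/2 for integer n")
  }
  m <- matrix(0, n, n)
  m[lower.tri(m)] <- v
  m <- t(m)
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  base::diag(m) <- diag
  m
}

#' Pair index map for an n-bin matrix
#'
#' @param n number of bins.
#' @return tibble with columns `idx` (position in the vectorized upper
#'   triangle), `i`, `j` (1-based bin indices, `i < j`).
#' @export
upper_pairs <- function(n) {
  i <- rep(seq_len(n - 1), times = (n - 1):1)
  j <- sequence((n - 1):1, from = 2:n)
  tibble::tibble(idx = seq_along(i), i = i, j = j)
}
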