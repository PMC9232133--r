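#' 2D mean filter (2DMF)
#'
#' Replaces each entry by the unweighted mean of the entries in its clipped
#' Chebyshev window of the given radius (center included) — the simplest of
#' the three reference data-quality-improvement smoothers.
#'
#' @param m symmetric contact matrix.
#' @param radius window radius in bins (default 2).
#' @return continuous symmetric matrix of the same size.
#' @export
mean_filter_2d <- function(m, radius = 2) {
  m <- unclass(as.matrix(m))
  if (!isSymmetric(unname(m), tol = 1e-8)) stop("input must be symmetric")
  if (radius == 0) {
    return(m)
  }
  box_sum(m, radius) / box_count(nrow(m), ncol(m), radius)
}

#' 2D Gaussian kernel filter (2DGK)
#'
#' Weighted window mean with weights proportional to
#' \eqn{\exp(-(\Delta i^2 + \Delta j^2) / (2 sd^2))}, renormalized over the
#' in-bounds part of the window.
#'
#' @param m symmetric contact matrix.
#' @param radius window radius in bins (default 2).
#' @param sd Gaussian bandwidth in bin units (default 1).
#' @return continuous symmetric matrix.
#' @export
gaussian_filter_2d <- function(m, radius = 2, sd = 1) {
  m <- unclass(as.matrix(m))
  if (!isSymmetric(unname(m), tol = 1e-8)) stop("input must be symmetric")
  if (sd <= 0) stop("sd must be positive")
  off <- seq(-radius, radius)
  w1 <- exp(-off^2 / (2 * sd^2))
  # separable kernel: weighted row pass then column pass, each tracking the
  # in-bounds weight mass for renormalization at the borders
  pass <- function(x) {
    num <- matrix(0, nrow(x), ncol(x))
    den <- matrix(0, nrow(x), ncol(x))
    for (d in seq_along(off)) {
      sh <- off[d]
      src <- seq_len(nrow(x)) + sh
      keep <- src >= 1 & src <= nrow(x)
      num[keep, ] <- num[keep, ] + w1[d] * x[src[keep], ]
      den[keep, ] <- den[keep, ] + w1[d]
    }
    list(num = num, den = den)
  }
  r1 <- pass(m)
  r2n <- pass(t(r1$num))
  r2d <- pass(t(r1$den))
  t(r2n$num) / t(r2d$num)
}

#' Three-step random-walk smoother (RW3S)
#'
#' Row-normalizes the matrix into a transition matrix `P` (rows summing to
#' zero become uniform), takes `steps` steps of the walk, restores the
#' original row scale and symmetrizes:
#' \eqn{R = (D P^s + (D P^s)^\top) / 2} with `D = diag(row sums)`. Three
#' steps is the recommended setting; `steps = 0` returns the input.
#'
#' @param m symmetric contact matrix with at least one nonzero row sum.
#' @param steps number of walk steps (default 3).
#' @return continuous symmetric matrix; total mass is preserved up to the
#'   symmetrization.
#' @export
random_walk_3 <- function(m, steps = 3) {
  m <- unclass(as.matrix(m))
  if (!isSymmetric(unname(m), tol = 1e-8)) stop("input must be symmetric")
  rs <- rowSums(m)
  if (all(rs == 0)) stop("all-zero matrix")
  if (steps == 0) {
    return(m)
  }
  P <- m / ifelse(rs == 0, 1, rs)
  P[rs == 0, ] <- 1 / ncol(m)
  Ps <- diag(nrow(m))
  for (s in seq_len(steps)) Ps <- Ps %*% P
  R <- rs * Ps
  (R + t(R)) / 2
}

#' Threshold-based structural-zero calls for smoothed matrices
#'
#' The value-threshold adaptation used to compare the smoothers with the
#' Bayesian model: an observed zero is labelled a structural zero when the
#' smoothed (imputed) value is strictly below the threshold (default 0.5 on
#' the original count scale). Sweeping the threshold produces the smoothers'
#' ROC curves.
#'
#' @param imputed continuous smoothed matrix.
#' @param observed observed contact matrix of the same size.
#' @param threshold call threshold (default 0.5).
#' @return logical matrix of structural-zero calls (diagonal excluded).
#' @export
call_sz_by_value <- function(imputed, observed, threshold = 0.5) {
  imputed <- unclass(as.matrix(imputed))
  observed <- unclass(as.matrix(observed))
  if (!all(dim(imputed) == dim(observed))) {
    stop("imputed and observed differ in shape")
  }
  calls <- (observed == 0) & (imputed < threshold)
  diag(calls) <- FALSE
  calls
}

#' Apply a named baseline smoother to every cell of a group
#'
#' @param group a [schic_group()].
#' @param method `"2dmf"`, `"2dgk"` or `"rw3s"`.
#' @param radius,sd,steps smoother parameters.
#' @return named list of continuous matrices, one per cell.
#' @export
smooth_group <- function(group, method = c("2dmf", "2dgk", "rw3s"),
                         radius = 2, sd = 1, steps = 3) {
  method <- match.arg(method)
  out <- lapply(group$cells, function(m) {
    switch(method,
      "2dmf" = mean_filter_2d(m, radius),
      "2dgk" = gaussian_filter_2d(m, radius, sd),
      "rw3s" = random_walk_3(m, steps)
    )
  })
  names(out) <- group$labels
  out
}
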