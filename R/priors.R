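#' Lattice neighborhood specification
#'
#' The model borrows local information through square (Chebyshev-ball)
#' windows on the contact-matrix lattice:
#' \eqn{\Omega(i,j) = \{(i',j'): \max(|i-i'|, |j-j'|) \le r\}} clipped at the
#' matrix borders. The default radius 2 takes the two immediate neighbors (if
#' available) in all directions.
#'
#' @param radius nonnegative integer lattice radius (default 2).
#' @param include_center include the center position itself (default `TRUE`).
#' @return list of class `neighborhood_spec`.
#' @export
neighborhood_spec <- function(radius = 2, include_center = TRUE) {
  if (radius < 0 || radius != round(radius)) {
    stop("radius must be a nonnegative integer")
  }
  structure(
    list(radius = as.integer(radius), include_center = isTRUE(include_center)),
    class = "neighborhood_spec"
  )
}

# Window sums over clipped Chebyshev windows via a summed-area table.
box_sum <- function(m, radius) {
  n <- nrow(m); p <- ncol(m)
  cs <- apply(m, 2, cumsum)
  cs <- rbind(0, cs)
  cs <- t(apply(cs, 1, cumsum))
  cs <- cbind(0, cs) # cs[i+1, j+1] = sum m[1:i, 1:j]
  r1 <- pmax(seq_len(n) - radius, 1L); r2 <- pmin(seq_len(n) + radius, n)
  c1 <- pmax(seq_len(p) - radius, 1L); c2 <- pmin(seq_len(p) + radius, p)
  cs[r2 + 1L, c2 + 1L] - cs[r1, c2 + 1L] - cs[r2 + 1L, c1] + cs[r1, c1]
}

# Number of in-bounds window positions per matrix entry.
box_count <- function(n, p, radius) {
  box_sum(matrix(1, n, p), radius)
}

window_mean <- function(m, nbr) {
  s <- box_sum(m, nbr$radius)
  cnt <- box_count(nrow(m), ncol(m), nbr$radius)
  if (!nbr$include_center) {
    s <- s - m
    cnt <- cnt - 1
  }
  s / cnt
}

#' Neighborhood-informed prior summaries
#'
#' Computes, per pair, the quantities feeding the model's priors:
#' * `y_nsc` — depth-weighted single-cell average
#'   \eqn{Y^{(nSC)}_{ij} = \sum_k Y_{ijk} / \sum_k \lambda^k}, the pooled
#'   count normalized to the target depth \eqn{T};
#' * `y_nb` — bulk count normalized to \eqn{T},
#'   \eqn{Y^{(nB)}_{ij} = T\, Y^b_{ij} / T_b} (absent without bulk);
#' * `ybar_nsc` — the grand mean of `y_nsc` over all pairs `i < j`;
#' * `prior_mean_mu` — the mean of the Gamma prior on the pair intensity
#'   \eqn{\mu_{ij}}. With bulk it is the bulk window mean re-weighted by how
#'   the local single-cell window mean compares with the grand mean:
#'   \deqn{m_{0,ij} = \Big(\tfrac{1}{\|\Omega_2\|}\sum_{\Omega_2} Y^{(nB)}\Big)
#'     \Big(\tfrac{1}{\|\Omega_1\|\,\bar Y^{(nSC)}}\sum_{\Omega_1} Y^{(nSC)}\Big),}
#'   so a locally rich single-cell neighborhood boosts the bulk prior and a
#'   poor one shrinks it. Without bulk it reduces to the single-cell window
#'   mean. Zero prior means are floored at `eps`;
#' * `zero_prop` — observed proportion of zeros across cells per pair.
#'
#' @param group a [schic_group()].
#' @param nbr a [neighborhood_spec()].
#' @param eps positive floor for the prior mean (default 0.01).
#' @return list of class `schic_priors` with the matrices above.
#' @export
compute_prior_summaries <- function(group, nbr = neighborhood_spec(),
                                    eps = 0.01) {
  stopifnot(inherits(group, "schic_group"))
  K <- length(group$cells)
  ysum <- Reduce(`+`, lapply(group$cells, unclass))
  y_nsc <- ysum / sum(group$lambdas)
  ybar_nsc <- mean(y_nsc[upper.tri(y_nsc)])
  wm_nsc <- window_mean(y_nsc, nbr)
  if (!is.null(group$bulk)) {
    t_b <- matrix_depth(group$bulk)
    if (t_b <= 0) stop("bulk matrix has zero depth")
    y_nb <- group$target_depth * unclass(group$bulk) / t_b
    wm_nb <- window_mean(y_nb, nbr)
    prior_mean_mu <- wm_nb * (wm_nsc / ybar_nsc)
  } else {
    y_nb <- NULL
    prior_mean_mu <- wm_nsc
  }
  prior_mean_mu <- pmax(prior_mean_mu, eps)
  zero_prop <- Reduce(`+`, lapply(group$cells, function(m) unclass(m) == 0)) / K
  structure(
    list(
      y_nsc = y_nsc, y_nb = y_nb, ybar_nsc = ybar_nsc,
      prior_mean_mu = prior_mean_mu, zero_prop = zero_prop,
      nbr = nbr, eps = eps
    ),
    class = "schic_priors"
  )
}

#' Per-pair dispersion from nonzero neighborhood counts
#'
#' \eqn{\sigma^2_{ij}} — the (squared) sample standard deviation of the
#' nonzero single-cell counts pooled over the window \eqn{\Omega_1(i,j)} and
#' over all cells. It is computed once from the data and held fixed during
#' sampling. Where fewer than two nonzero counts exist, or the pooled counts
#' are constant (sd 0), the value falls back to `floor`.
#'
#' @param group a [schic_group()].
#' @param nbr a [neighborhood_spec()].
#' @param floor fallback/floor value (default 1).
#' @return matrix of per-pair variances.
#' @export
compute_sigma2 <- function(group, nbr = neighborhood_spec(), floor = 1) {
  stopifnot(inherits(group, "schic_group"))
  s1 <- Reduce(`+`, lapply(group$cells, function(m) box_sum(unclass(m), nbr$radius)))
  s2 <- Reduce(`+`, lapply(group$cells, function(m) box_sum(unclass(m)^2, nbr$radius)))
  nn <- Reduce(`+`, lapply(group$cells, function(m) {
    box_sum(matrix(as.numeric(unclass(m) > 0), nrow(m)), nbr$radius)
  }))
  v <- matrix(floor, group$n_bins, group$n_bins)
  ok <- nn >= 2
  v[ok] <- (s2[ok] - s1[ok]^2 / nn[ok]) / (nn[ok] - 1)
  v[!is.finite(v) | v <= 0] <- floor
  v
}

#' Beta prior for the structural-zero probability
#'
#' The per-pair probability \eqn{\pi_{ij}} that loci `i` and `j` never
#' interact gets a Beta prior whose mean equals the observed proportion of
#' zeros across cells at that pair (clipped away from 0 and 1): with shared
#' shape `a` and clipped proportion \eqn{m_{ij}}, the second shape is
#' \eqn{b_{ij} = a (1 - m_{ij}) / m_{ij}}, so that
#' \eqn{E[\pi_{ij}] = m_{ij}}. Positions that are mostly zero across cells
#' are thus a priori more likely structural.
#'
#' @param group a [schic_group()].
#' @param a shared Beta shape (hyperparameter; sampled by the MCMC).
#' @param eps clip for the zero proportion; default `1 / (2K)`.
#' @return list with matrices `mean` (clipped zero proportion), `a`, `b`.
#' @export
zero_proportion_prior <- function(group, a = 1, eps = NULL) {
  stopifnot(inherits(group, "schic_group"))
  K <- length(group$cells)
  if (is.null(eps)) eps <- 1 / (2 * K)
  zp <- Reduce(`+`, lapply(group$cells, function(m) unclass(m) == 0)) / K
  m <- pmin(pmax(zp, eps), 1 - eps)
  list(mean = m, a = a, b = a * (1 - m) / m)
}
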