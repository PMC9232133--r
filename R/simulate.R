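#' Stand-in 3D chromatin chain
#'
#' Generates a connected 3D polymer chain to play the role of a reconstructed
#' single-cell 3D structure. Two kinds are available:
#' * `"helix"` — a unit-arc-step helix whose radius, pitch and phase are
#'   drawn from the seed, giving a smooth, reproducible structure with
#'   constant inter-locus step length;
#' * `"smooth_random_walk"` — a random walk whose increments are smoothed
#'   with a moving-average momentum and rescaled to unit steps.
#'
#' Distinct seeds give distinct structures, which is how simulated cell
#' types are made to differ.
#'
#' @param n number of loci (chain length).
#' @param kind `"helix"` or `"smooth_random_walk"`.
#' @param seed integer seed; same seed, same coordinates.
#' @return `n x 3` matrix of coordinates.
#' @export
make_structure <- function(n, kind = c("helix", "smooth_random_walk"),
                           seed = 1) {
  kind <- match.arg(kind)
  if (n < 2) stop("need at least 2 loci")
  set.seed(seed)
  if (kind == "helix") {
    r <- stats::runif(1, 0.7, 1.6)
    turns <- stats::runif(1, 1.5, 4)
    phase <- stats::runif(1, 0, 2 * pi)
    theta <- phase + seq(0, turns * 2 * pi, length.out = n)
    dtheta <- theta[2] - theta[1]
    # pick pitch so consecutive loci are unit-distance apart
    chord <- 2 * r * sin(dtheta / 2)
    dz <- sqrt(max(1 - chord^2, 0.01))
    coords <- cbind(r * cos(theta), r * sin(theta), dz * seq_len(n))
  } else {
    steps <- matrix(stats::rnorm(3 * (n - 1)), ncol = 3)
    w <- 5 # momentum window keeps the walk locally straight
    sm <- apply(steps, 2, function(s) stats::filter(c(rep(s[1], w - 1), s),
      rep(1 / w, w),
      sides = 1
    )[w:(n + w - 2)])
    sm <- sm / sqrt(rowSums(sm^2))
    coords <- rbind(0, apply(sm, 2, cumsum))
  }
  d <- as.matrix(stats::dist(coords))
  if (any(d[upper.tri(d)] <= 0)) stop("degenerate structure: duplicate points")
  unname(coords)
}

#' Pairwise Euclidean distance matrix
#'
#' @param coords `n x 3` coordinate matrix.
#' @return symmetric distance matrix with zero diagonal.
#' @export
distance_matrix <- function(coords) {
  if (anyNA(coords) || any(!is.finite(coords))) stop("coordinates must be finite")
  d <- as.matrix(stats::dist(coords))
  if (any(d[upper.tri(d)] == 0)) {
    stop("duplicate points give zero distance; log-distance model undefined")
  }
  unname(d)
}

#' Intensity matrix from a 3D structure
#'
#' Builds the expected-contact intensity surface from the biophysical
#' power-law model with locus covariates:
#' \deqn{\log \lambda_{ij} = \alpha_0 + \alpha_1 \log d_{ij}
#'   + \beta_l \log(x_{l,i} x_{l,j}) + \beta_g \log(x_{g,i} x_{g,j})
#'   + \beta_m \log(x_{m,i} x_{m,j}),}
#' with \eqn{\alpha_1 = -1} (contact probability inversely proportional to
#' distance) and per-locus covariates mimicking fragment length, GC content
#' and mappability drawn from a uniform range. The matrix is then rescaled so
#' the upper-triangle total equals `target_depth`, the expected sequencing
#' depth of one cell.
#'
#' @param d distance matrix (positive off-diagonal).
#' @param alpha0 scale coefficient (cell-type level, e.g. 5.7 / 6.3 / 6.8).
#' @param alpha1 distance exponent (default -1).
#' @param betas length-3 covariate coefficients (default 0.9 each).
#' @param cov_range uniform range for the three covariates (default
#'   `c(0.2, 1)`).
#' @param target_depth expected total count over pairs `i < j`; `NULL` skips
#'   rescaling.
#' @param covariates optional `n x 3` matrix to reuse fixed covariates.
#' @return symmetric intensity matrix (zero diagonal) with attribute
#'   `covariates`.
#' @export
lambda_matrix <- function(d, alpha0, alpha1 = -1, betas = c(0.9, 0.9, 0.9),
                          cov_range = c(0.2, 1), target_depth = NULL,
                          covariates = NULL) {
  n <- nrow(d)
  if (any(d[upper.tri(d)] <= 0)) stop("distances must be positive for i < j")
  if (is.null(covariates)) {
    covariates <- matrix(stats::runif(3 * n, cov_range[1], cov_range[2]), ncol = 3)
  }
  if (any(covariates <= 0)) stop("covariates must be positive")
  loglam <- alpha0 + alpha1 * log(d)
  for (c3 in 1:3) {
    loglam <- loglam + betas[c3] * log(outer(covariates[, c3], covariates[, c3]))
  }
  lam <- exp(loglam)
  diag(lam) <- 0
  if (!is.null(target_depth)) {
    lam <- lam * target_depth / sum(lam[upper.tri(lam)])
  }
  attr(lam, "covariates") <- covariates
  lam
}

#' Choose structural-zero candidate positions
#'
#' From the intensity surface, takes the `floor(gamma * P)` pairs with the
#' smallest intensities (the lower \eqn{\gamma}-quantile band, ties broken by
#' pair order), declares a uniformly random half of them candidates, and
#' promotes a uniformly random \eqn{\eta} fraction of the candidates to
#' common structural zeros shared by every cell of the type; the remaining
#' candidates are per-cell candidates, zeroed independently per cell by a
#' fair coin at sampling time. All selection counts use floor rounding.
#'
#' @param lambda intensity matrix.
#' @param gamma lower-quantile fraction defining the candidate band
#'   (default 0.10).
#' @param eta fraction of candidates promoted to common structural zeros
#'   (default 0.80).
#' @return list with pair-index vectors (into [upper_pairs()] order)
#'   `below_idx`, `candidate_idx`, `common_sz_idx`, `percell_candidate_idx`
#'   and the logical matrices `common_sz_mask`, `percell_candidate_mask`.
#' @export
assign_zero_candidates <- function(lambda, gamma = 0.10, eta = 0.80) {
  if (gamma < 0 || gamma >= 1 || eta < 0 || eta > 1) {
    stop("gamma must be in [0,1) and eta in [0,1]")
  }
  n <- nrow(lambda)
  v <- vectorize_upper(unclass(lambda))
  P <- length(v)
  n_below <- floor(gamma * P)
  below <- order(v)[seq_len(n_below)]
  n_cand <- floor(n_below / 2)
  candidates <- if (n_cand > 0) sort(sample(below, n_cand)) else integer(0)
  n_common <- floor(eta * n_cand)
  common <- if (n_common > 0) sort(sample(candidates, n_common)) else integer(0)
  percell <- setdiff(candidates, common)
  to_mask <- function(idx) {
    z <- logical(P)
    z[idx] <- TRUE
    devectorize_upper(z, n) > 0
  }
  list(
    below_idx = sort(below), candidate_idx = candidates,
    common_sz_idx = common, percell_candidate_idx = percell,
    common_sz_mask = to_mask(common),
    percell_candidate_mask = to_mask(percell)
  )
}

#' Simulate one cell from an intensity surface and zero masks
#'
#' The per-cell intensity \eqn{\lambda^*} zeroes out the common structural
#' zeros and an independent fair-coin selection of the per-cell candidates;
#' counts are then independent Poisson draws. Zeros where \eqn{\lambda^* = 0}
#' are the cell's structural zeros; zeros where \eqn{\lambda^* > 0} are its
#' dropouts.
#'
#' @param lambda intensity matrix (before any zeroing).
#' @param common_sz_mask logical matrix of shared structural zeros.
#' @param percell_candidate_mask logical matrix of per-cell candidates.
#' @return list with `counts` (integer contact matrix), `lambda_star`,
#'   `sz_mask`, `do_mask`.
#' @export
sample_cell <- function(lambda, common_sz_mask, percell_candidate_mask) {
  n <- nrow(lambda)
  lam_v <- vectorize_upper(unclass(lambda))
  common_v <- vectorize_upper(common_sz_mask) > 0
  cand_v <- vectorize_upper(percell_candidate_mask) > 0
  own <- cand_v & (stats::runif(length(lam_v)) < 0.5)
  star <- ifelse(common_v | own, 0, lam_v)
  cnt <- stats::rpois(length(star), star)
  counts <- devectorize_upper(cnt, n)
  lambda_star <- devectorize_upper(star, n)
  sz <- lambda_star == 0
  diag(sz) <- FALSE
  list(
    counts = contact_matrix(counts),
    lambda_star = lambda_star,
    sz_mask = sz,
    do_mask = lambda_star > 0 & counts == 0
  )
}

#' Pool cells into a bulk matrix
#'
#' @param cells list of contact matrices on identical bins.
#' @return entry-wise sum as a `contact_matrix`.
#' @export
make_bulk <- function(cells) {
  if (length(cells) == 0) stop("no cells to pool")
  dims <- vapply(cells, nrow, integer(1))
  if (length(unique(dims)) != 1) stop("dimension mismatch across cells")
  contact_matrix(Reduce(`+`, lapply(cells, unclass)), label = "bulk")
}

#' Simulate a single-cell Hi-C group with known zero labels
#'
#' The full generative pipeline for one cell type: a stand-in 3D chain
#' ([make_structure()]), its distance matrix, the power-law intensity surface
#' rescaled to the target depth ([lambda_matrix()]), structural-zero
#' assignment ([assign_zero_candidates()]) and Poisson sampling of each cell
#' ([sample_cell()]). Optionally builds a companion bulk matrix the way a
#' population experiment would: by pooling `bulk_cells_per_type` simulated
#' cells from each of three cell types (this type plus two others with their
#' own structures and scale coefficients), 540 cells in total by default.
#'
#' @param n_cells number of single cells (default 10).
#' @param n_bins matrix dimension (default 61).
#' @param alpha0 scale coefficient of this cell type (default 5.7).
#' @param target_depth expected per-cell depth (default 4000).
#' @param gamma,eta structural-zero assignment fractions (defaults 0.10,
#'   0.80).
#' @param alpha1,betas,cov_range see [lambda_matrix()].
#' @param structure chain kind, see [make_structure()].
#' @param structure_seed seed of the 3D chain (cell-type identity); defaults
#'   to `seed`.
#' @param seed master seed for covariates, masks and counts.
#' @param bulk `"none"` or `"pooled"` (pool three simulated cell types).
#' @param bulk_cells_per_type cells per type pooled into bulk (default 180).
#' @param bulk_alpha0 scale coefficients of the two companion types
#'   (default `c(6.3, 6.8)`).
#' @return list of class `schic_sim` with `group` (a [schic_group()]) and
#'   `truth` (class `sim_truth`): `lambda` (post-common-mask base intensity),
#'   `common_sz_mask`, per-cell lists `lambda_star`, `sz_mask`, `do_mask`,
#'   `expected` (= `lambda_star`), plus the parameters.
#' @export
simulate_schic <- function(n_cells = 10, n_bins = 61, alpha0 = 5.7,
                           target_depth = 4000, gamma = 0.10, eta = 0.80,
                           alpha1 = -1, betas = c(0.9, 0.9, 0.9),
                           cov_range = c(0.2, 1),
                           structure = c("helix", "smooth_random_walk"),
                           structure_seed = NULL, seed = 1,
                           bulk = c("none", "pooled"),
                           bulk_cells_per_type = 180,
                           bulk_alpha0 = c(6.3, 6.8)) {
  structure_kind <- match.arg(structure)
  bulk <- match.arg(bulk)
  if (is.null(structure_seed)) structure_seed <- seed
  coords <- make_structure(n_bins, structure_kind, seed = structure_seed)
  d <- distance_matrix(coords)
  set.seed(seed)
  lam <- lambda_matrix(d, alpha0,
    alpha1 = alpha1, betas = betas,
    cov_range = cov_range, target_depth = target_depth
  )
  zc <- assign_zero_candidates(lam, gamma, eta)
  cells <- vector("list", n_cells)
  lambda_star <- sz_mask <- do_mask <- vector("list", n_cells)
  for (k in seq_len(n_cells)) {
    sc <- sample_cell(lam, zc$common_sz_mask, zc$percell_candidate_mask)
    cells[[k]] <- sc$counts
    lambda_star[[k]] <- sc$lambda_star
    sz_mask[[k]] <- sc$sz_mask
    do_mask[[k]] <- sc$do_mask
  }
  bulk_m <- NULL
  if (bulk == "pooled") {
    pool <- list()
    type_alpha0 <- c(alpha0, bulk_alpha0)
    for (ty in seq_along(type_alpha0)) {
      if (ty == 1) {
        lam_t <- lam
        zc_t <- zc
      } else {
        coords_t <- make_structure(n_bins, structure_kind,
          seed = structure_seed + ty * 1000L
        )
        set.seed(seed + ty * 1000L)
        lam_t <- lambda_matrix(distance_matrix(coords_t), type_alpha0[ty],
          alpha1 = alpha1, betas = betas, cov_range = cov_range,
          target_depth = target_depth
        )
        zc_t <- assign_zero_candidates(lam_t, gamma, eta)
      }
      pool <- c(pool, lapply(seq_len(bulk_cells_per_type), function(k) {
        sample_cell(lam_t, zc_t$common_sz_mask, zc_t$percell_candidate_mask)$counts
      }))
    }
    bulk_m <- make_bulk(pool)
  }
  lambda_base <- lam
  lambda_base[zc$common_sz_mask] <- 0
  structure(
    list(
      group = schic_group(cells, bulk = bulk_m),
      truth = structure(
        list(
          lambda = lambda_base, common_sz_mask = zc$common_sz_mask,
          percell_candidate_mask = zc$percell_candidate_mask,
          lambda_star = lambda_star, sz_mask = sz_mask, do_mask = do_mask,
          expected = lambda_star
        ),
        class = "sim_truth"
      ),
      params = list(
        n_cells = n_cells, n_bins = n_bins, alpha0 = alpha0,
        target_depth = target_depth, gamma = gamma, eta = eta,
        alpha1 = alpha1, betas = betas, cov_range = cov_range,
        structure = structure_kind, structure_seed = structure_seed,
        seed = seed, bulk = bulk
      )
    ),
    class = "schic_sim"
  )
}

#' @export
print.schic_sim <- function(x, ...) {
  p <- x$params
  cat("<schic_sim> ", p$n_cells, " cells, ", p$n_bins, " bins, alpha0 = ",
    p$alpha0, ", target depth ", p$target_depth, "\n",
    sep = ""
  )
  cat(
    "  common structural zeros: ",
    sum(x$truth$common_sz_mask[upper.tri(x$truth$common_sz_mask)]),
    " pairs\n",
    sep = ""
  )
  invisible(x)
}
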