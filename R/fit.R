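#' Fit the zero-inflated Poisson hierarchy to a single-cell Hi-C group
#'
#' The model treats each observed count \eqn{Y_{ijk}} (pair `i < j`, cell `k`)
#' as a mixture of a point mass at zero — the structural-zero state, loci that
#' never interact in that cell — and a Poisson component
#' \eqn{\mathrm{Poisson}(\lambda^k \mu_{ijk})}, where \eqn{\lambda^k} is the
#' cell's proportionate sequencing depth. The structural-zero probability
#' \eqn{\pi_{ij}} gets a Beta prior centered on the observed zero proportion
#' across cells ([zero_proportion_prior()]); cell intensities \eqn{\mu_{ijk}}
#' are positive-truncated normal around a pair intensity \eqn{\mu_{ij}} with
#' data-derived dispersion ([compute_sigma2()]); and \eqn{\mu_{ij}} has a
#' Gamma prior whose mean blends the bulk and single-cell neighborhood
#' signal ([compute_prior_summaries()]). Shared shapes `a` (Beta) and `alpha`
#' (Gamma) get Gamma(1, 1) hyperpriors.
#'
#' Inference is Metropolis-within-Gibbs: exact Bernoulli/Beta updates for the
#' zero indicators and \eqn{\pi_{ij}}, log-scale random-walk Metropolis for
#' the intensity blocks and hyperparameters, with proposal scales adapted
#' during burn-in. A zero of cell `k` is called structural when the posterior
#' mean \eqn{\hat\pi_{ij}} exceeds `sz_threshold` (default 0.5, the Bayes
#' rule); dropout zeros and observed nonzeros are imputed by the posterior
#' mean of \eqn{\lambda^k \mu_{ijk}} on the observed count scale.
#'
#' @param group a [schic_group()].
#' @param radius,include_center neighborhood window, see
#'   [neighborhood_spec()].
#' @param n_iter,burn_in,thin MCMC length controls (defaults 3000/1500/1).
#' @param n_chains number of independent chains (default 1). Extra chains
#'   start from different RNG states; posterior summaries pool all chains'
#'   post-burn-in draws and [mcmc_traces()] returns every chain for
#'   convergence inspection.
#' @param seed integer seed; the fit is bit-reproducible given all inputs and
#'   the seed.
#' @param sz_threshold posterior-mean threshold for the structural-zero call.
#' @param sigma2_floor floor/fallback for \eqn{\sigma^2_{ij}}.
#' @param eps_prior floor for the Gamma prior mean.
#' @param eps_clip clip for the zero proportion; default `1/(2K)`.
#' @param hyper_a,hyper_alpha length-2 `c(shape, rate)` Gamma hyperpriors for
#'   `a` and `alpha`.
#' @param trace_pairs optional 2-column matrix / data frame of (i, j) pairs
#'   whose full \eqn{\pi} and \eqn{\mu} chains are kept for diagnostics.
#' @param fix_mu internal testing hook: a single value or per-pair vector at
#'   which all intensities are held fixed (collapses the sampler to the
#'   \eqn{(S, \pi)} subchain).
#' @param fix_hyper hold `a` and `alpha` at their initial values (testing).
#' @param a_init,alpha_init initial hyperparameter values.
#'
#' @return object of class `schic_fit` with elements `pi_hat` (matrix of
#'   posterior means), `mu_hat`, `mu_cell_hat` (pairs x cells), `sz_mask`
#'   (pair-level call \eqn{\hat\pi >} threshold), `sz_calls` (per-cell list of
#'   logical matrices over observed zeros), `imputed` (per-cell improved
#'   matrices), `s_freq`, `accept`, `traces`, and the fit configuration.
#' @seealso [tidy.schic_fit()], [glance.schic_fit()],
#'   [call_structural_zeros()], [impute_cells()]
#' @export
schic_impute <- function(group,
                         radius = 2, include_center = TRUE,
                         n_iter = 3000, burn_in = 1500, thin = 1,
                         n_chains = 1, seed = NULL, sz_threshold = 0.5,
                         sigma2_floor = 1, eps_prior = 0.01,
                         eps_clip = NULL,
                         hyper_a = c(1, 1), hyper_alpha = c(1, 1),
                         trace_pairs = NULL,
                         fix_mu = NULL, fix_hyper = FALSE,
                         a_init = 1, alpha_init = 1) {
  stopifnot(inherits(group, "schic_group"))
  if (burn_in >= n_iter) stop("burn_in must be smaller than n_iter")
  if (sz_threshold <= 0 || sz_threshold >= 1) stop("sz_threshold must be in (0,1)")
  nbr <- neighborhood_spec(radius, include_center)
  n <- group$n_bins
  K <- length(group$cells)
  pairs <- upper_pairs(n)

  pri <- compute_prior_summaries(group, nbr, eps = eps_prior)
  sig2 <- compute_sigma2(group, nbr, floor = sigma2_floor)
  zp <- zero_proportion_prior(group, a = a_init, eps = eps_clip)

  Y <- vapply(group$cells, vectorize_upper, numeric(nrow(pairs)))
  storage.mode(Y) <- "integer"
  m0 <- vectorize_upper(pri$prior_mean_mu)
  s2 <- vectorize_upper(sig2)
  mz <- vectorize_upper(zp$mean)

  trace_idx <- integer(0)
  if (!is.null(trace_pairs)) {
    tp <- as.matrix(trace_pairs)
    trace_idx <- vapply(seq_len(nrow(tp)), function(r) {
      ii <- min(tp[r, 1], tp[r, 2]); jj <- max(tp[r, 1], tp[r, 2])
      which(pairs$i == ii & pairs$j == jj)
    }, integer(1)) - 1L
  }

  mu_init <- numeric(0)
  if (!is.null(fix_mu)) {
    mu_init <- rep_len(as.numeric(fix_mu), nrow(pairs))
  }

  if (!is.null(seed)) set.seed(seed)
  chains <- lapply(seq_len(n_chains), function(ch) {
    .zip_mcmc_cpp(
      Y, group$lambdas, as.numeric(m0), as.numeric(s2), as.numeric(mz),
      as.integer(n_iter), as.integer(burn_in), as.integer(thin),
      a_init, alpha_init,
      hyper_a[1], hyper_a[2], hyper_alpha[1], hyper_alpha[2],
      !is.null(fix_mu), mu_init, isTRUE(fix_hyper), trace_idx
    )
  })
  res <- chains[[1]]
  if (n_chains > 1) {
    # pool posterior summaries across chains (equal kept-draw counts)
    for (fld in c("pi_hat", "mu_pair_hat", "mu_cell_hat", "s_freq",
                  "a_hat", "alpha_hat")) {
      res[[fld]] <- Reduce(`+`, lapply(chains, `[[`, fld)) / n_chains
    }
  }

  pi_hat <- devectorize_upper(res$pi_hat, n)
  mu_hat <- devectorize_upper(res$mu_pair_hat, n)
  sz_mask <- pi_hat > sz_threshold
  diag(sz_mask) <- FALSE

  sz_calls <- vector("list", K)
  imputed <- vector("list", K)
  for (k in seq_len(K)) {
    obs <- unclass(group$cells[[k]])
    calls <- (obs == 0) & sz_mask
    diag(calls) <- FALSE
    imp <- devectorize_upper(
      group$lambdas[k] * res$mu_cell_hat[, k], n,
      diag = diag(obs)
    )
    imp[calls] <- 0
    sz_calls[[k]] <- calls
    imputed[[k]] <- contact_matrix(imp,
      integral = FALSE,
      label = group$labels[k]
    )
  }
  names(sz_calls) <- names(imputed) <- group$labels

  structure(
    list(
      pi_hat = pi_hat, mu_hat = mu_hat,
      mu_cell_hat = res$mu_cell_hat,
      sz_mask = sz_mask, sz_calls = sz_calls, imputed = imputed,
      s_freq = res$s_freq,
      a_hat = res$a_hat, alpha_hat = res$alpha_hat,
      accept = res$accept, traces = res$traces,
      chain_traces = lapply(chains, `[[`, "traces"),
      prior = pri, sigma2 = sig2, group = group, pairs = pairs,
      config = list(
        radius = radius, include_center = include_center,
        n_iter = n_iter, burn_in = burn_in, thin = thin,
        n_chains = n_chains,
        seed = seed, sz_threshold = sz_threshold,
        sigma2_floor = sigma2_floor, eps_prior = eps_prior,
        eps_clip = eps_clip, n_kept = res$n_kept
      )
    ),
    class = "schic_fit"
  )
}

#' @export
print.schic_fit <- function(x, ...) {
  cat("<schic_fit> ", x$group$n_bins, " bins, ", length(x$group$cells),
    " cells, ", x$config$n_iter, " iterations (", x$config$n_kept,
    " kept)\n",
    sep = ""
  )
  cat(
    "  structural-zero pairs called at threshold ",
    x$config$sz_threshold, ": ", sum(x$sz_mask[upper.tri(x$sz_mask)]), "\n",
    sep = ""
  )
  invisible(x)
}

#' Mixture log-density of one observation
#'
#' The observation model for a single pair and cell: in the structural-zero
#' state (`s = 1`) the count is a point mass at zero; otherwise it is Poisson
#' with intensity `lam_k * mu_ijk`.
#'
#' @param y observed count.
#' @param s structural-zero indicator (0 or 1).
#' @param lam_k proportionate depth of the cell.
#' @param mu_ijk positive cell intensity (required when `s = 0`).
#' @return log density; `-Inf` for the impossible configuration `s = 1, y > 0`.
#' @export
zip_loglik <- function(y, s, lam_k, mu_ijk) {
  if (s == 1) {
    return(if (y == 0) 0 else -Inf)
  }
  stopifnot(mu_ijk > 0)
  stats::dpois(y, lam_k * mu_ijk, log = TRUE)
}

#' Call structural zeros from a fitted model
#'
#' For every cell and every pair with an observed zero, the zero is declared
#' structural when the posterior mean of \eqn{\pi_{ij}} exceeds the
#' threshold (strictly); observed nonzeros are never structural.
#'
#' @param fit a [schic_impute()] result.
#' @param threshold call threshold in (0, 1), default the fit's
#'   `sz_threshold`.
#' @return named list (per cell) of logical call matrices.
#' @export
call_structural_zeros <- function(fit, threshold = NULL) {
  stopifnot(inherits(fit, "schic_fit"))
  if (is.null(threshold)) threshold <- fit$config$sz_threshold
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0,1)")
  mask <- fit$pi_hat > threshold
  diag(mask) <- FALSE
  out <- lapply(fit$group$cells, function(m) {
    calls <- (unclass(m) == 0) & mask
    diag(calls) <- FALSE
    calls
  })
  names(out) <- fit$group$labels
  out
}

#' Improved (imputed) matrices from a fit
#'
#' Returns the per-cell improved matrices: structural-zero calls are exact
#' zeros; dropout zeros and observed nonzeros carry the posterior mean of
#' \eqn{\lambda^k \mu_{ijk}} (observed count scale). With a non-default
#' `threshold` the structural-zero mask is recomputed first.
#'
#' @inheritParams call_structural_zeros
#' @return named list of continuous `contact_matrix` objects.
#' @export
impute_cells <- function(fit, threshold = NULL) {
  stopifnot(inherits(fit, "schic_fit"))
  if (is.null(threshold) || identical(threshold, fit$config$sz_threshold)) {
    return(fit$imputed)
  }
  calls <- call_structural_zeros(fit, threshold)
  n <- fit$group$n_bins
  out <- lapply(seq_along(fit$group$cells), function(k) {
    obs <- unclass(fit$group$cells[[k]])
    imp <- devectorize_upper(
      fit$group$lambdas[k] * fit$mu_cell_hat[, k], n,
      diag = diag(obs)
    )
    imp[calls[[k]]] <- 0
    contact_matrix(imp, integral = FALSE, label = fit$group$labels[k])
  })
  names(out) <- fit$group$labels
  out
}

#' Per-pair posterior summaries as a tibble
#'
#' @param x a `schic_fit`.
#' @param ... unused.
#' @return tibble with one row per pair `i < j`: posterior means `pi_hat`,
#'   `mu_hat`, the prior inputs `zero_prop` and `prior_mean_mu`, and the
#'   pair-level call `sz_pair`.
#' @method tidy schic_fit
#' @export
tidy.schic_fit <- function(x, ...) {
  dplyr::mutate(
    x$pairs,
    pi_hat = vectorize_upper(x$pi_hat)[idx],
    mu_hat = vectorize_upper(x$mu_hat)[idx],
    zero_prop = vectorize_upper(x$prior$zero_prop)[idx],
    prior_mean_mu = vectorize_upper(x$prior$prior_mean_mu)[idx],
    sz_pair = vectorize_upper(x$sz_mask)[idx] > 0
  )
}

#' One-row fit summary
#'
#' @param x a `schic_fit`.
#' @param ... unused.
#' @return one-row tibble: problem size, chain length, hyperparameter
#'   posterior means, Metropolis acceptance rates, and the number of
#'   structural-zero pairs called.
#' @method glance schic_fit
#' @export
glance.schic_fit <- function(x, ...) {
  tibble::tibble(
    n_bins = x$group$n_bins,
    n_pairs = nrow(x$pairs),
    n_cells = length(x$group$cells),
    n_iter = x$config$n_iter,
    burn_in = x$config$burn_in,
    a_hat = x$a_hat,
    alpha_hat = x$alpha_hat,
    accept_mu_cell = x$accept$mu_cell,
    accept_mu_pair = x$accept$mu_pair,
    accept_a = x$accept$a,
    accept_alpha = x$accept$alpha,
    n_sz_pairs = sum(x$sz_mask[upper.tri(x$sz_mask)])
  )
}

#' MCMC traces for selected pairs as a long tibble
#'
#' @param fit a [schic_impute()] result fitted with `trace_pairs`.
#' @return tibble with columns `chain`, `iteration`, `parameter`, `pair`,
#'   `value`; hyperparameters `a` and `alpha` are always traced.
#' @export
mcmc_traces <- function(fit) {
  stopifnot(inherits(fit, "schic_fit"))
  purrr::map_dfr(seq_along(fit$chain_traces), function(ch) {
    tr <- fit$chain_traces[[ch]]
    n_iter <- length(tr$a)
    out <- tibble::tibble(
      chain = ch,
      iteration = rep(seq_len(n_iter), 2),
      parameter = rep(c("a", "alpha"), each = n_iter),
      pair = NA_character_,
      value = c(tr$a, tr$alpha)
    )
    if (!is.null(dim(tr$pi)) && ncol(tr$pi) > 0) {
      extra <- purrr::map_dfr(seq_len(ncol(tr$pi)), function(t) {
        tibble::tibble(
          chain = ch,
          iteration = rep(seq_len(n_iter), 2),
          parameter = rep(c("pi", "mu_pair"), each = n_iter),
          pair = paste0("trace", t),
          value = c(tr$pi[, t], tr$mu_pair[, t])
        )
      })
      out <- dplyr::bind_rows(out, extra)
    }
    out
  })
}
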