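# MCMC correctness checks on tiny groups where independent numerical
# integration of the posterior is feasible.

test_that("mixture log-density: point mass, Poisson branch, impossible state", {
  expect_equal(zip_loglik(0, s = 1, lam_k = 1, mu_ijk = 2), 0)
  expect_equal(
    zip_loglik(3, s = 0, lam_k = 1, mu_ijk = 3),
    -3 + 3 * log(3) - log(6)
  )
  expect_equal(zip_loglik(5, s = 1, lam_k = 1, mu_ijk = 2), -Inf)
})

test_that("fits are bit-identical under a fixed seed", {
  g <- tiny_group(bulk = TRUE)
  f1 <- schic_impute(g, n_iter = 400, burn_in = 200, seed = 7)
  f2 <- schic_impute(g, n_iter = 400, burn_in = 200, seed = 7)
  expect_identical(f1$pi_hat, f2$pi_hat)
  expect_identical(f1$mu_cell_hat, f2$mu_cell_hat)
  expect_identical(f1$imputed, f2$imputed)
  f3 <- schic_impute(g, n_iter = 400, burn_in = 200, seed = 8)
  expect_false(identical(f1$pi_hat, f3$pi_hat))
})

test_that("structural-zero indicator is never 1 for a nonzero observation", {
  g <- tiny_group()
  fit <- schic_impute(g, n_iter = 600, burn_in = 200, seed = 3)
  for (k in seq_along(g$cells)) {
    y <- vectorize_upper(g$cells[[k]])
    expect_true(all(fit$s_freq[y > 0, k] == 0))
  }
  # posterior means of pi stay in [0, 1]
  expect_true(all(fit$pi_hat >= 0 & fit$pi_hat <= 1))
  # Metropolis blocks actually move on non-degenerate data
  expect_gt(fit$accept$mu_cell, 0)
  expect_lt(fit$accept$mu_cell, 1)
})

test_that("collapsed pi posterior matches 1-D numerical integration", {
  # 10 cells, 3 bins; pair (1,3) is zero in every cell, pair (2,3) in four.
  # With all intensities fixed at mu0 and hyperparameters held, the sampler
  # reduces to the exact (S, pi) Gibbs subchain whose marginal is available
  # by quadrature:
  #   p(pi | y) propto Beta(pi; a, b) prod_zero (pi + (1-pi) e^{-lam_k mu0})
  #                    * (1 - pi)^{#nonzero}
  K <- 10
  mu0 <- 1.3
  a <- 1.5
  y23 <- c(0, 0, 0, 0, 2, 1, 3, 2, 1, 2)
  cells <- lapply(seq_len(K), function(k) sym_mat(c(5, 0, y23[k]), 3))
  g <- schic_group(cells)
  fit <- schic_impute(g,
    n_iter = 12000, burn_in = 2000, seed = 99,
    fix_mu = mu0, fix_hyper = TRUE, a_init = a
  )

  post_mean_pi <- function(n_zero, n_nonzero, lam, m) {
    b <- a * (1 - m) / m
    lik <- function(p) {
      vapply(p, function(pp) {
        prod(pp + (1 - pp) * exp(-lam[seq_len(n_zero)] * mu0)) *
          (1 - pp)^n_nonzero
      }, numeric(1))
    }
    # integrate against the Beta prior via its quantile transform, which
    # absorbs the b < 1 edge singularity
    ef <- function(f) {
      stats::integrate(function(u) f(stats::qbeta(u, a, b)),
        0, 1,
        rel.tol = 1e-10
      )$value
    }
    ef(function(p) p * lik(p)) / ef(lik)
  }

  m13 <- 1 - 1 / (2 * K) # clipped zero proportion, all cells zero
  expect_equal(fit$pi_hat[1, 3], post_mean_pi(K, 0, g$lambdas, m13),
    tolerance = 0.02
  )
  m23 <- 4 / K
  expect_equal(fit$pi_hat[2, 3],
    post_mean_pi(4, 6, g$lambdas[y23 == 0], m23),
    tolerance = 0.02
  )
})

test_that("cell intensity posterior matches 2-D grid integration", {
  # one cell, so S = 0 is forced at the nonzero pair; holding a and alpha,
  # the (mu_ijk, mu_ij) block has density
  #   Pois(y; lam mu) Normal+(mu; mp, s2) Gamma(mp; alpha, alpha/m0)
  # integrable on a grid.
  y <- 6
  cells <- list(sym_mat(c(y, 2, 3), 3))
  g <- schic_group(cells)
  fit <- schic_impute(g,
    n_iter = 20000, burn_in = 4000, seed = 123,
    fix_hyper = TRUE, a_init = 1, alpha_init = 1
  )
  pri <- compute_prior_summaries(g)
  s2 <- compute_sigma2(g)
  m0 <- pri$prior_mean_mu[1, 2]
  sig2 <- s2[1, 2]
  alpha <- 1

  mu <- seq(0.01, 30, length.out = 600)
  mp <- seq(0.01, 30, length.out = 600)
  lpost <- outer(mu, mp, function(u, v) {
    stats::dpois(y, u, log = TRUE) +
      stats::dnorm(u, v, sqrt(sig2), log = TRUE) -
      stats::pnorm(v / sqrt(sig2), log.p = TRUE) +
      stats::dgamma(v, alpha, rate = alpha / m0, log = TRUE)
  })
  w <- exp(lpost - max(lpost))
  mu_mean <- sum(mu * rowSums(w)) / sum(w)
  expect_equal(fit$mu_cell_hat[1, 1], mu_mean, tolerance = 0.05)
})

test_that("structural-zero calls are strict and monotone in the threshold", {
  g <- tiny_group()
  fit <- schic_impute(g, n_iter = 500, burn_in = 200, seed = 5)
  fit$pi_hat[1, 2] <- fit$pi_hat[2, 1] <- 0.5
  calls <- call_structural_zeros(fit, threshold = 0.5)
  expect_false(any(vapply(calls, function(m) m[1, 2], logical(1))))

  counts <- vapply(seq(0.05, 0.95, by = 0.05), function(t) {
    sum(vapply(call_structural_zeros(fit, t), sum, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
  # nonzero observations are never called
  for (k in seq_along(g$cells)) {
    expect_false(any(calls[[k]][unclass(g$cells[[k]]) > 0]))
  }
})

test_that("imputed matrices honor the call semantics", {
  g <- tiny_group(bulk = TRUE)
  fit <- schic_impute(g, n_iter = 800, burn_in = 300, seed = 11)
  for (k in seq_along(g$cells)) {
    obs <- unclass(g$cells[[k]])
    imp <- unclass(fit$imputed[[k]])
    expect_true(all(imp >= 0))
    expect_true(all(imp[fit$sz_calls[[k]]] == 0)) # structural zeros stay 0
    do_zeros <- obs == 0 & !fit$sz_calls[[k]] & upper.tri(obs)
    expect_true(all(imp[do_zeros] > 0)) # dropouts get positive values
  }
  # a non-default threshold re-derives calls and zeros consistently
  imp2 <- impute_cells(fit, threshold = 0.9)
  calls2 <- call_structural_zeros(fit, 0.9)
  expect_true(all(unclass(imp2[[1]])[calls2[[1]]] == 0))
})

test_that("multiple chains pool summaries and expose per-chain traces", {
  g <- tiny_group()
  fit <- schic_impute(g,
    n_iter = 300, burn_in = 100, n_chains = 3, seed = 13,
    trace_pairs = cbind(1, 3)
  )
  expect_length(fit$chain_traces, 3)
  tr <- mcmc_traces(fit)
  expect_setequal(unique(tr$chain), 1:3)
  # chains differ (different RNG states) but pooled pi stays a probability
  expect_false(identical(fit$chain_traces[[1]]$a, fit$chain_traces[[2]]$a))
  expect_true(all(fit$pi_hat >= 0 & fit$pi_hat <= 1))
  # pooled mean equals the average of per-fit single chains run back to back
  set.seed(13)
  one <- schic_impute(g, n_iter = 300, burn_in = 100, n_chains = 1)
  expect_identical(fit$chain_traces[[1]]$a, one$chain_traces[[1]]$a)
})
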