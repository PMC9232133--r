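#include <Rcpp.h>
using namespace Rcpp;

// Metropolis-within-Gibbs sampler for the zero-inflated Poisson hierarchy on
// vectorized pair data.
//
// Per pair p (i < j) and cell k:
//   Y_pk | S_pk = 0 ~ Poisson(lam_k * mu_pk),  Y_pk | S_pk = 1 ~ delta_0
//   S_pk ~ Bernoulli(pi_p)
//   pi_p ~ Beta(a, b_p),           b_p = a (1 - m_p) / m_p
//   mu_pk ~ Normal+(mu_p, sig2_p)  (truncated to positive reals)
//   mu_p  ~ Gamma(alpha, rate = alpha / m0_p)   (mean m0_p)
//   a ~ Gamma(ha_shape, ha_rate),  alpha ~ Gamma(halpha_shape, halpha_rate)
//
// sig2_p is fixed from the data. Exact Gibbs draws for S and pi; log-scale
// Gaussian random-walk Metropolis for mu_pk, mu_p, a and alpha, with scales
// adapted in batches during burn-in. Uses R's RNG, so results are
// reproducible under set.seed().

static inline double log_trunc_norm_kernel(double x, double mean, double sig2) {
  // positive-truncated normal log density without the normalizing constant
  // that depends only on (mean, sig2): used where the constant cancels.
  return -0.5 * (x - mean) * (x - mean) / sig2;
}

static inline double log_phi_ratio(double mean, double sd) {
  // log P(N(mean, sd^2) > 0) = log Phi(mean / sd)
  return R::pnorm(mean / sd, 0.0, 1.0, 1, 1);
}

// [[Rcpp::export(name = ".zip_mcmc_cpp")]]
List zip_mcmc_cpp(IntegerMatrix Y, NumericVector lam, NumericVector m0,
                  NumericVector sig2, NumericVector mzero,
                  int n_iter, int burn_in, int thin,
                  double a_init, double alpha_init,
                  double ha_shape, double ha_rate,
                  double halpha_shape, double halpha_rate,
                  bool fix_mu, NumericVector mu_init,
                  bool fix_hyper, IntegerVector trace_idx) {
  const int P = Y.nrow(), K = Y.ncol();
  if (burn_in >= n_iter) stop("burn_in must be < n_iter");

  NumericVector pi(P), mu_p(P), b(P), sd_p(P);
  NumericMatrix mu_c(P, K);
  IntegerMatrix S(P, K);
  double a = a_init, alpha = alpha_init;

  for (int p = 0; p < P; ++p) {
    pi[p] = mzero[p];
    mu_p[p] = std::max(m0[p], 0.05);
    sd_p[p] = std::sqrt(sig2[p]);
    for (int k = 0; k < K; ++k) {
      double yn = Y(p, k) / std::max(lam[k], 1e-12);
      mu_c(p, k) = std::max(std::max(yn, mu_p[p]), 0.05);
      if (fix_mu) mu_c(p, k) = mu_init[p];
      S(p, k) = (Y(p, k) == 0 && unif_rand() < mzero[p]) ? 1 : 0;
    }
    if (fix_mu) mu_p[p] = mu_init[p];
  }

  // proposal scales (log-scale random walks) and acceptance bookkeeping
  NumericMatrix sc_mc(P, K);
  NumericVector sc_mp(P, 0.5);
  std::fill(sc_mc.begin(), sc_mc.end(), 0.5);
  double sc_a = 0.3, sc_alpha = 0.3;
  NumericMatrix try_mc(P, K), acc_mc(P, K);
  NumericVector try_mp(P), acc_mp(P);
  double try_a = 0, acc_a = 0, try_alpha = 0, acc_alpha = 0;
  const int batch = 50;

  // posterior accumulators
  NumericVector sum_pi(P), sum_mu_p(P);
  NumericMatrix sum_mu_c(P, K), s_freq(P, K);
  double sum_a = 0, sum_alpha = 0;
  int n_kept = 0;

  const int n_tr = trace_idx.size();
  NumericMatrix tr_pi(n_iter, n_tr), tr_mu(n_iter, n_tr);
  NumericVector tr_a(n_iter), tr_alpha(n_iter);

  for (int it = 0; it < n_iter; ++it) {
    bool tuning = it < burn_in;
    for (int p = 0; p < P; ++p) {
      // --- S: exact Bernoulli full conditional, only where Y == 0 ---
      int sumS = 0;
      for (int k = 0; k < K; ++k) {
        if (Y(p, k) == 0) {
          double pz = pi[p] /
            (pi[p] + (1.0 - pi[p]) * std::exp(-lam[k] * mu_c(p, k)));
          S(p, k) = (unif_rand() < pz) ? 1 : 0;
        } else {
          S(p, k) = 0;
        }
        sumS += S(p, k);
      }
      // --- pi: Beta full conditional ---
      b[p] = a * (1.0 - mzero[p]) / mzero[p];
      pi[p] = R::rbeta(a + sumS, b[p] + K - sumS);
      if (pi[p] < 1e-12) pi[p] = 1e-12;
      if (pi[p] > 1.0 - 1e-12) pi[p] = 1.0 - 1e-12;

      if (!fix_mu) {
        // --- mu_pk: log-scale RW Metropolis ---
        for (int k = 0; k < K; ++k) {
          double cur = mu_c(p, k);
          double prop = cur * std::exp(sc_mc(p, k) * norm_rand());
          double ll = log_trunc_norm_kernel(prop, mu_p[p], sig2[p]) -
                      log_trunc_norm_kernel(cur, mu_p[p], sig2[p]);
          if (S(p, k) == 0) {
            ll += R::dpois(Y(p, k), lam[k] * prop, 1) -
                  R::dpois(Y(p, k), lam[k] * cur, 1);
          }
          ll += std::log(prop) - std::log(cur); // Jacobian of log-scale walk
          try_mc(p, k) += 1;
          if (std::log(unif_rand()) < ll) {
            mu_c(p, k) = prop;
            acc_mc(p, k) += 1;
          }
        }
        // --- mu_p: log-scale RW Metropolis ---
        {
          double cur = mu_p[p];
          double prop = cur * std::exp(sc_mp[p] * norm_rand());
          double ll = 0.0;
          for (int k = 0; k < K; ++k) {
            ll += log_trunc_norm_kernel(mu_c(p, k), prop, sig2[p]) -
                  log_trunc_norm_kernel(mu_c(p, k), cur, sig2[p]);
          }
          ll -= K * (log_phi_ratio(prop, sd_p[p]) -
                     log_phi_ratio(cur, sd_p[p]));
          double rate = alpha / m0[p];
          ll += (alpha - 1.0) * (std::log(prop) - std::log(cur)) -
                rate * (prop - cur);
          ll += std::log(prop) - std::log(cur);
          try_mp[p] += 1;
          if (std::log(unif_rand()) < ll) {
            mu_p[p] = prop;
            acc_mp[p] += 1;
          }
        }
      }
    }

    if (!fix_hyper) {
      // --- a: shared Beta shape ---
      {
        double prop = a * std::exp(sc_a * norm_rand());
        double ll = 0.0;
        for (int p = 0; p < P; ++p) {
          double bp_cur = a * (1.0 - mzero[p]) / mzero[p];
          double bp_prop = prop * (1.0 - mzero[p]) / mzero[p];
          ll += (std::lgamma(prop + bp_prop) - std::lgamma(prop) -
                 std::lgamma(bp_prop)) -
                (std::lgamma(a + bp_cur) - std::lgamma(a) -
                 std::lgamma(bp_cur));
          ll += (prop - a) * std::log(pi[p]) +
                (bp_prop - bp_cur) * std::log(1.0 - pi[p]);
        }
        ll += (ha_shape - 1.0) * (std::log(prop) - std::log(a)) -
              ha_rate * (prop - a);
        ll += std::log(prop) - std::log(a);
        try_a += 1;
        if (std::log(unif_rand()) < ll) { a = prop; acc_a += 1; }
      }
      // --- alpha: shared Gamma shape ---
      {
        double prop = alpha * std::exp(sc_alpha * norm_rand());
        double ll = 0.0;
        for (int p = 0; p < P; ++p) {
          double lr_prop = std::log(prop / m0[p]);
          double lr_cur = std::log(alpha / m0[p]);
          ll += (prop * lr_prop - std::lgamma(prop) +
                 (prop - 1.0) * std::log(mu_p[p]) - (prop / m0[p]) * mu_p[p]) -
                (alpha * lr_cur - std::lgamma(alpha) +
                 (alpha - 1.0) * std::log(mu_p[p]) -
                 (alpha / m0[p]) * mu_p[p]);
        }
        ll += (halpha_shape - 1.0) * (std::log(prop) - std::log(alpha)) -
              halpha_rate * (prop - alpha);
        ll += std::log(prop) - std::log(alpha);
        try_alpha += 1;
        if (std::log(unif_rand()) < ll) { alpha = prop; acc_alpha += 1; }
      }
    }

    // --- batch adaptation toward 20-50% acceptance, burn-in only ---
    if (tuning && ((it + 1) % batch == 0)) {
      double step = 0.2;
      for (int p = 0; p < P; ++p) {
        for (int k = 0; k < K; ++k) {
          if (try_mc(p, k) > 0) {
            double r = acc_mc(p, k) / try_mc(p, k);
            if (r > 0.5) sc_mc(p, k) *= std::exp(step);
            else if (r < 0.2) sc_mc(p, k) *= std::exp(-step);
          }
          try_mc(p, k) = acc_mc(p, k) = 0;
        }
        if (try_mp[p] > 0) {
          double r = acc_mp[p] / try_mp[p];
          if (r > 0.5) sc_mp[p] *= std::exp(step);
          else if (r < 0.2) sc_mp[p] *= std::exp(-step);
        }
        try_mp[p] = acc_mp[p] = 0;
      }
      if (try_a > 0) {
        double r = acc_a / try_a;
        if (r > 0.5) sc_a *= std::exp(step);
        else if (r < 0.2) sc_a *= std::exp(-step);
        try_a = acc_a = 0;
      }
      if (try_alpha > 0) {
        double r = acc_alpha / try_alpha;
        if (r > 0.5) sc_alpha *= std::exp(step);
        else if (r < 0.2) sc_alpha *= std::exp(-step);
        try_alpha = acc_alpha = 0;
      }
    }
    // --- traces (full chains for selected pairs) ---
    for (int t = 0; t < n_tr; ++t) {
      tr_pi(it, t) = pi[trace_idx[t]];
      tr_mu(it, t) = mu_p[trace_idx[t]];
    }
    tr_a[it] = a;
    tr_alpha[it] = alpha;

    // --- posterior accumulation ---
    if (it >= burn_in && ((it - burn_in) % thin == 0)) {
      ++n_kept;
      for (int p = 0; p < P; ++p) {
        sum_pi[p] += pi[p];
        sum_mu_p[p] += mu_p[p];
        for (int k = 0; k < K; ++k) {
          sum_mu_c(p, k) += mu_c(p, k);
          s_freq(p, k) += S(p, k);
        }
      }
      sum_a += a;
      sum_alpha += alpha;
    }
  }

  // post-burn-in acceptance rates from the (reset) batch counters
  double post_acc_mc = 0, post_acc_mp = 0;
  double post_try_mc = 0, post_try_mp = 0;
  for (int p = 0; p < P; ++p) {
    post_try_mp += try_mp[p]; post_acc_mp += acc_mp[p];
    for (int k = 0; k < K; ++k) {
      post_try_mc += try_mc(p, k); post_acc_mc += acc_mc(p, k);
    }
  }

  for (int p = 0; p < P; ++p) {
    sum_pi[p] /= n_kept;
    sum_mu_p[p] /= n_kept;
    for (int k = 0; k < K; ++k) {
      sum_mu_c(p, k) /= n_kept;
      s_freq(p, k) /= n_kept;
    }
  }

  return List::create(
    _["pi_hat"] = sum_pi,
    _["mu_pair_hat"] = sum_mu_p,
    _["mu_cell_hat"] = sum_mu_c,
    _["s_freq"] = s_freq,
    _["a_hat"] = sum_a / n_kept,
    _["alpha_hat"] = sum_alpha / n_kept,
    _["n_kept"] = n_kept,
    _["accept"] = List::create(
      _["mu_cell"] = post_try_mc > 0 ? post_acc_mc / post_try_mc : NA_REAL,
      _["mu_pair"] = post_try_mp > 0 ? post_acc_mp / post_try_mp : NA_REAL,
      _["a"] = try_a > 0 ? acc_a / try_a : NA_REAL,
      _["alpha"] = try_alpha > 0 ? acc_alpha / try_alpha : NA_REAL),
    _["traces"] = List::create(
      _["pi"] = tr_pi, _["mu_pair"] = tr_mu,
      _["a"] = tr_a, _["alpha"] = tr_alpha)
  );
}
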