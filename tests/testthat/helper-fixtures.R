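# Small deterministic fixtures shared across test files.

# symmetric integer matrix with zero diagonal
sym_mat <- function(v, n, diag = 0) {
  devectorize_upper(v, n, diag = diag)
}

# a tiny two-cell group on 5 bins with a known structure of zeros
tiny_group <- function(bulk = FALSE) {
  c1 <- sym_mat(c(3, 0, 0, 1, 2, 0, 0, 4, 1, 0), 5)
  c2 <- sym_mat(c(2, 1, 0, 0, 3, 0, 1, 2, 0, 0), 5)
  b <- if (bulk) sym_mat(c(30, 8, 1, 6, 25, 2, 5, 33, 9, 1), 5)
  schic_group(list(c1, c2), bulk = b)
}

# random symmetric nonnegative integer matrix
rand_sym <- function(n, lambda = 2, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sym_mat(rpois(n * (n - 1) / 2, lambda), n, diag = rpois(n, lambda))
}

# brute-force windowed filter oracle (double loop over the window)
brute_filter <- function(m, radius, weight_fun = NULL) {
  n <- nrow(m)
  out <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      acc <- 0
      wacc <- 0
      for (di in -radius:radius) {
        for (dj in -radius:radius) {
          ii <- i + di
          jj <- j + dj
          if (ii >= 1 && ii <= n && jj >= 1 && jj <= n) {
            w <- if (is.null(weight_fun)) 1 else weight_fun(di, dj)
            acc <- acc + w * m[ii, jj]
            wacc <- wacc + w
          }
        }
      }
      out[i, j] <- acc / wacc
    }
  }
  out
}
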