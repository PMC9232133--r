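test_that("stand-in structures are reproducible, connected, non-degenerate", {
  for (kind in c("helix", "smooth_random_walk")) {
    co <- make_structure(61, kind, seed = 5)
    expect_equal(dim(co), c(61, 3))
    expect_identical(co, make_structure(61, kind, seed = 5))
    expect_false(identical(co, make_structure(61, kind, seed = 6)))
    d <- distance_matrix(co)
    expect_true(all(d[upper.tri(d)] > 0))
  }
  # helix: constant step length between consecutive loci
  co <- make_structure(40, "helix", seed = 2)
  steps <- sqrt(rowSums(diff(co)^2))
  expect_equal(steps, rep(steps[1], 39), tolerance = 1e-8)
})

test_that("distance matrix basics and triangle inequality", {
  co <- rbind(c(0, 0, 0), c(1, 0, 0), c(3, 4, 0))
  d <- distance_matrix(co)
  expect_equal(d[1, 2], 1)
  expect_equal(d[1, 3], 5) # 3-4-5 triangle
  expect_true(isSymmetric(d))
  expect_equal(diag(d), rep(0, 3))
  set.seed(8)
  co2 <- matrix(rnorm(30), ncol = 3)
  d2 <- distance_matrix(co2)
  for (i in 1:10) {
    for (j in 1:10) {
      for (k in 1:10) {
        expect_lte(d2[i, j], d2[i, k] + d2[k, j] + 1e-12)
      }
    }
  }
  expect_error(distance_matrix(rbind(c(0, 0, 0), c(0, 0, 0))), "duplicate")
})

test_that("intensity surface follows the power law and hits the target depth", {
  d <- distance_matrix(make_structure(20, "helix", seed = 3))
  cov1 <- matrix(1, 20, 3)
  # all covariates 1 and unit distance: lambda = exp(alpha0) before rescaling
  lam <- lambda_matrix(d / d[1, 2], alpha0 = 2, covariates = cov1)
  expect_equal(lam[1, 2], exp(2))
  # alpha1 = -1: doubling the distance halves the intensity
  lam2 <- lambda_matrix(2 * d, alpha0 = 2, covariates = cov1)
  lam1 <- lambda_matrix(d, alpha0 = 2, covariates = cov1)
  expect_equal(lam2[upper.tri(lam2)], lam1[upper.tri(lam1)] / 2)
  # rescaling pins the expected depth
  set.seed(4)
  lam3 <- lambda_matrix(d, alpha0 = 5.7, target_depth = 4000)
  expect_equal(sum(lam3[upper.tri(lam3)]), 4000)
  # covariates enter through log(x_i x_j)
  set.seed(5)
  lam4 <- lambda_matrix(d, alpha0 = 0, betas = c(1, 0, 0))
  x <- attr(lam4, "covariates")[, 1]
  expect_equal(lam4[2, 5], exp(-log(d[2, 5]) + log(x[2] * x[5])))
})

test_that("candidate bookkeeping uses floor rounding at each stage", {
  d <- distance_matrix(make_structure(61, "helix", seed = 1))
  set.seed(2)
  lam <- lambda_matrix(d, alpha0 = 5.7, target_depth = 4000)
  zc <- assign_zero_candidates(lam, gamma = 0.10, eta = 0.80)
  expect_length(zc$below_idx, 183) # floor(0.10 * 1830)
  expect_length(zc$candidate_idx, 91) # floor(183 / 2)
  expect_length(zc$common_sz_idx, 72) # floor(0.80 * 91)
  expect_length(zc$percell_candidate_idx, 19)
  # nesting: common SZ within candidates within the low-intensity band
  expect_true(all(zc$common_sz_idx %in% zc$candidate_idx))
  expect_true(all(zc$candidate_idx %in% zc$below_idx))
  # the band really is the lowest-intensity pairs
  v <- vectorize_upper(lam)
  expect_lte(max(v[zc$below_idx]), min(v[-zc$below_idx]))
  # gamma = 0 selects nothing
  zc0 <- assign_zero_candidates(lam, gamma = 0, eta = 0.8)
  expect_length(zc0$candidate_idx, 0)
})

test_that("per-cell sampling partitions observed zeros into SZ and DO", {
  d <- distance_matrix(make_structure(31, "helix", seed = 6))
  set.seed(7)
  lam <- lambda_matrix(d, alpha0 = 5.7, target_depth = 1000)
  zc <- assign_zero_candidates(lam, 0.2, 0.5)
  set.seed(8)
  sc <- sample_cell(lam, zc$common_sz_mask, zc$percell_candidate_mask)
  ut <- upper.tri(lam)
  zeros <- unclass(sc$counts) == 0 & ut
  # every observed zero is exactly one of SZ / DO
  expect_true(all(xor(sc$sz_mask[zeros], sc$do_mask[zeros])))
  expect_false(any(sc$sz_mask & sc$do_mask))
  # counts vanish wherever lambda* is zero
  expect_true(all(unclass(sc$counts)[sc$lambda_star == 0] == 0))
  # common SZs are shared; per-cell SZs eventually differ between cells
  expect_true(all(sc$sz_mask[zc$common_sz_mask]))
  set.seed(9)
  diffs <- vapply(1:20, function(r) {
    a <- sample_cell(lam, zc$common_sz_mask, zc$percell_candidate_mask)
    b <- sample_cell(lam, zc$common_sz_mask, zc$percell_candidate_mask)
    sum(a$sz_mask != b$sz_mask)
  }, numeric(1))
  expect_gt(sum(diffs), 0)
})

test_that("realized depth concentrates on the target", {
  sim <- simulate_schic(n_cells = 50, n_bins = 61, target_depth = 4000, seed = 12)
  depths <- sim$group$depths
  # expected depth = sum(lambda*), slightly under the 4000 pre-mask target
  exp_depth <- mean(vapply(sim$truth$lambda_star, function(l) {
    sum(l[upper.tri(l)])
  }, numeric(1)))
  expect_lt(abs(mean(depths) - exp_depth), 3 * sd(depths) / sqrt(50))
  expect_lt(abs(mean(depths) - 4000), 3 * sd(depths))
  # sparsity rises as depth falls
  sim_lo <- simulate_schic(n_cells = 10, target_depth = 2000, seed = 13)
  sim_hi <- simulate_schic(n_cells = 10, target_depth = 7000, seed = 13)
  sp <- function(s) mean(vapply(s$group$cells, function(m) {
    mean(vectorize_upper(m) == 0)
  }, numeric(1)))
  expect_gt(sp(sim_lo), sp(sim_hi))
})

test_that("bulk pooling is entry-wise summation", {
  m1 <- sym_mat(c(1, 0, 0), 3)
  m2 <- sym_mat(c(2, 1, 0), 3)
  m3 <- sym_mat(c(3, 0, 2), 3)
  b <- make_bulk(list(m1, m2, m3))
  expect_equal(b[1, 2], 6)
  expect_equal(matrix_depth(b), sum(vapply(list(m1, m2, m3), matrix_depth, numeric(1))))
  expect_error(make_bulk(list(m1, sym_mat(c(1), 2))), "dimension")
  # the pooled-bulk simulation draws three cell types
  sim <- simulate_schic(
    n_cells = 2, n_bins = 15, target_depth = 300,
    seed = 3, bulk = "pooled", bulk_cells_per_type = 5
  )
  expect_false(is.null(sim$group$bulk))
  expect_gt(matrix_depth(sim$group$bulk), 0)
})

test_that("simulation truth is reproducible by seed", {
  s1 <- simulate_schic(n_cells = 3, n_bins = 21, target_depth = 500, seed = 42)
  s2 <- simulate_schic(n_cells = 3, n_bins = 21, target_depth = 500, seed = 42)
  expect_identical(
    lapply(s1$group$cells, unclass),
    lapply(s2$group$cells, unclass)
  )
  expect_identical(s1$truth$common_sz_mask, s2$truth$common_sz_mask)
  expect_identical(s1$truth$do_mask, s2$truth$do_mask)
})
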