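make_masks <- function(true_sz, called, n = 4) {
  list(truth = sym_mat(true_sz, n) > 0, calls = sym_mat(called, n) > 0)
}

test_that("PTSZ counts recovered structural zeros", {
  m <- make_masks(c(1, 1, 1, 1, 0, 0), c(1, 1, 1, 1, 0, 0))
  expect_equal(ptsz(m$truth, m$calls), 1)
  m2 <- make_masks(c(1, 1, 1, 1, 0, 0), c(1, 1, 1, 0, 0, 0))
  expect_equal(ptsz(m2$truth, m2$calls), 0.75)
  m3 <- make_masks(c(1, 1, 1, 1, 0, 0), rep(0, 6))
  expect_equal(ptsz(m3$truth, m3$calls), 0)
  # no true SZs: undefined
  m4 <- make_masks(rep(0, 6), rep(0, 6))
  expect_true(is.nan(ptsz(m4$truth, m4$calls)))
  expect_error(ptsz(m$truth, sym_mat(rep(0, 3), 3) > 0), "shape")
})

test_that("PTDO counts dropouts left uncalled", {
  do <- c(1, 1, 1, 1, 1, 1, 1, 1, 1, 1)
  m <- make_masks(do, rep(0, 10), n = 5)
  expect_equal(ptdo(m$truth, m$calls), 1)
  m2 <- make_masks(do, do, n = 5)
  expect_equal(ptdo(m2$truth, m2$calls), 0) # everything mis-called SZ
  m3 <- make_masks(do, c(1, rep(0, 9)), n = 5)
  expect_equal(ptdo(m3$truth, m3$calls), 0.9)
  # pooling across cells weights by per-cell counts
  two_truth <- list(m$truth, m$truth)
  two_calls <- list(m$calls, m2$calls)
  expect_equal(ptdo(two_truth, two_calls), 0.5)
  pc <- ptdo(two_truth, two_calls, per_cell = TRUE)
  expect_equal(pc$rate, c(1, 0))
})

test_that("absolute error and correlation metrics behave as defined", {
  ex <- sym_mat(c(3, 1, 2), 3)
  im_perfect <- ex
  expect_equal(abs_error(im_perfect, ex)$mean, 0)
  im_off <- ex + 1 - diag(1, 3) # +1 on all off-diagonal entries
  expect_equal(abs_error(im_off, ex)$mean, 1)
  # worked 2-entry case |2-3|, |0-1| over observed zeros
  obs <- sym_mat(c(0, 5, 0), 3)
  im <- sym_mat(c(2, 9, 0), 3)
  ex2 <- sym_mat(c(3, 9, 1), 3)
  expect_equal(
    abs_error(im, ex2, obs, mask = "observed_zeros")$mean,
    mean(c(1, 1))
  )
  expect_equal(imputation_cor(ex, ex)$mean, 1)
  expect_equal(imputation_cor(2 * ex + 1 - diag(1, 3), ex)$mean, 1) # affine
  anti <- sym_mat(c(1, 2, 3), 3)
  rev_anti <- sym_mat(c(3, 2, 1), 3)
  expect_equal(imputation_cor(anti, rev_anti)$mean, -1)
  expect_warning(
    imputation_cor(sym_mat(rep(1, 3), 3), ex),
    "zero variance"
  )
})

test_that("AUC equals the Mann-Whitney brute force, with symmetry", {
  set.seed(31)
  for (rep in 1:5) {
    n <- sample(20:200, 1)
    is_sz <- runif(n) < 0.4
    if (!any(is_sz) || all(is_sz)) next
    score <- rnorm(n) + is_sz * runif(1, 0, 2)
    if (rep >= 4) score <- round(score) # force heavy ties
    auc <- roc_auc(score, is_sz)$auc
    # brute force: P(score_SZ > score_DO) + 0.5 P(tie)
    cmp <- outer(score[is_sz], score[!is_sz], `-`)
    mw <- mean((cmp > 0) + 0.5 * (cmp == 0))
    expect_equal(auc, mw, tolerance = 1e-12)
    expect_equal(roc_auc(-score, is_sz)$auc, 1 - auc, tolerance = 1e-12)
  }
  # perfect separation
  expect_equal(roc_auc(c(1, 1, 0, 0), c(TRUE, TRUE, FALSE, FALSE))$auc, 1)
  # label-independent scores hover near 0.5 over replicates
  set.seed(32)
  aucs <- replicate(200, {
    roc_auc(rnorm(40), rep(c(TRUE, FALSE), 20))$auc
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.02)
  expect_error(roc_auc(1:3, c(TRUE, TRUE, TRUE)), "degenerate")
})

test_that("ROC endpoints and monotone trade-off", {
  set.seed(33)
  score <- rnorm(50)
  is_sz <- runif(50) < 0.5
  r <- roc_auc(score, is_sz)$roc
  expect_equal(r$sensitivity[1], 0)
  expect_equal(r$sensitivity[nrow(r)], 1)
  expect_equal(r$fpr[nrow(r)], 1)
  expect_true(all(diff(r$sensitivity) >= 0))
  expect_true(all(diff(r$ptdo) <= 0)) # PTSZ up, PTDO down
})

test_that("threshold calibration reaches the smallest sensitivity >= target", {
  score <- c(0.9, 0.8, 0.7, 0.6, 0.3, 0.2, 0.1)
  is_sz <- c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  cal <- calibrate_threshold_at_ptsz(score, is_sz, target_ptsz = 0.95)
  expect_equal(cal$ptsz, 1)
  expect_equal(cal$ptdo, 1) # perfectly separating scores
  # target 0: nothing needs calling, PTDO stays 1
  cal0 <- calibrate_threshold_at_ptsz(score, is_sz, target_ptsz = 0)
  expect_equal(cal0$ptdo, 1)
  # unreachable target on degenerate truth errors out
  expect_error(roc_auc(score, rep(TRUE, 7)), "degenerate")
})

test_that("metric suite on truth-as-calls reproduces the ideal report", {
  sim <- simulate_schic(n_cells = 4, n_bins = 31, target_depth = 1500, seed = 21)
  truth <- sim$truth
  expect_equal(ptsz(truth$sz_mask, truth$sz_mask), 1)
  expect_equal(ptdo(truth$do_mask, truth$sz_mask), 1)
  # imputing the exact expected surface gives zero error, perfect correlation
  ae <- abs_error(truth$expected, truth$expected,
    lapply(sim$group$cells, unclass),
    mask = "observed_zeros"
  )
  expect_equal(ae$mean, 0)
})

test_that("zero_scores collects one row per observed zero with truth labels", {
  sim <- simulate_schic(n_cells = 3, n_bins = 21, target_depth = 400, seed = 5)
  zs <- zero_scores(sim$group, sim$truth, matrix(0.5, 21, 21))
  n_zero <- sum(vapply(sim$group$cells, function(m) {
    sum(vectorize_upper(m) == 0)
  }, numeric(1)))
  expect_equal(nrow(zs), n_zero)
  expect_equal(
    sum(zs$is_sz),
    sum(vapply(sim$truth$sz_mask, function(m) sum(m[upper.tri(m)]), numeric(1)))
  )
})

test_that("full method report ranks the model above a smoother on all axes", {
  sim <- simulate_schic(
    n_cells = 4, n_bins = 31, target_depth = 1200,
    seed = 9, bulk = "pooled", bulk_cells_per_type = 10
  )
  fit <- schic_impute(sim$group, n_iter = 500, burn_in = 250, seed = 9)
  sm <- smooth_group(sim$group, "2dgk")
  rep <- evaluate_methods(sim, list(
    model = list(imputed = fit$imputed, calls = fit$sz_calls, scores = fit$pi_hat),
    gk = list(
      imputed = sm,
      calls = lapply(seq_along(sm), function(k) {
        call_sz_by_value(sm[[k]], sim$group$cells[[k]])
      }),
      scores = lapply(sm, function(x) -x)
    )
  ))
  expect_equal(rep$method, c("model", "gk"))
  expect_true(all(rep$ptsz >= 0 & rep$ptsz <= 1))
  expect_true(all(rep$auc >= 0 & rep$auc <= 1))
  expect_true(all(rep$aeoa >= 0 & rep$aeoz >= 0))
  expect_gt(rep$auc[1], rep$auc[2])
  expect_gt(rep$ptdo_at_target[1], rep$ptdo_at_target[2])
  # SEVI data covers every pair of every cell and flags observed zeros
  sd <- sevi_data(fit$imputed, sim$truth$expected, lapply(sim$group$cells, unclass))
  expect_equal(nrow(sd), 4 * choose(31, 2))
  expect_equal(
    sum(sd$observed_zero),
    sum(vapply(sim$group$cells, function(m) sum(vectorize_upper(m) == 0), numeric(1)))
  )
})
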