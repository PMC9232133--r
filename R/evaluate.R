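#' Sensitivity of structural-zero detection (PTSZ)
#'
#' Proportion of true structural zeros correctly identified, pooled over the
#' upper-triangle entries of all cells (or per cell with `per_cell = TRUE`).
#'
#' @param truth_sz list (per cell) of logical true structural-zero masks, or
#'   a single mask.
#' @param calls matching list (or mask) of structural-zero calls.
#' @param per_cell return a per-cell tibble instead of the pooled rate.
#' @return pooled rate in `[0, 1]` (`NaN` when there are no true structural
#'   zeros), or a tibble of per-cell rates.
#' @export
ptsz <- function(truth_sz, calls, per_cell = FALSE) {
  binary_rate(truth_sz, calls, flavor = "sz", per_cell = per_cell)
}

#' Specificity of structural-zero detection (PTDO)
#'
#' Proportion of true dropouts correctly identified, i.e. observed zeros that
#' truly arise from undersampling and are *not* called structural.
#'
#' @param truth_do list (per cell) of logical true dropout masks (observed
#'   zero with positive underlying intensity), or a single mask.
#' @inheritParams ptsz
#' @return pooled rate, or a per-cell tibble.
#' @export
ptdo <- function(truth_do, calls, per_cell = FALSE) {
  binary_rate(truth_do, calls, flavor = "do", per_cell = per_cell)
}

binary_rate <- function(truth, calls, flavor, per_cell) {
  if (is.matrix(truth)) truth <- list(truth)
  if (is.matrix(calls)) calls <- list(calls)
  if (length(truth) != length(calls)) stop("truth/calls length mismatch")
  one <- function(tm, cm) {
    if (!all(dim(tm) == dim(cm))) stop("mask shape mismatch")
    ut <- upper.tri(tm)
    denom <- sum(tm[ut])
    hit <- if (flavor == "sz") sum(tm[ut] & cm[ut]) else sum(tm[ut] & !cm[ut])
    c(hit = hit, denom = denom)
  }
  per <- vapply(seq_along(truth), function(k) one(truth[[k]], calls[[k]]),
    numeric(2)
  )
  if (per_cell) {
    return(tibble::tibble(
      cell = seq_along(truth),
      rate = per["hit", ] / per["denom", ],
      n_true = per["denom", ]
    ))
  }
  sum(per["hit", ]) / sum(per["denom", ])
}

#' Mean absolute imputation error (AEOA / AEOZ)
#'
#' Mean absolute difference between imputed and expected values, computed per
#' cell over the masked upper-triangle entries and then averaged (unweighted)
#' across cells. `mask = "all_observed"` gives the all-entries error (AEOA);
#' `"observed_zeros"` restricts to observed zeros (AEOZ).
#'
#' @param imputed list (per cell) of imputed matrices.
#' @param expected list of expected matrices (the simulator's
#'   \eqn{\lambda^*}).
#' @param observed list of observed count matrices (needed for the
#'   observed-zeros mask).
#' @param mask `"all_observed"` or `"observed_zeros"`.
#' @return list with `mean`, `se` (across cells) and `per_cell` tibble.
#' @export
abs_error <- function(imputed, expected, observed = NULL,
                      mask = c("all_observed", "observed_zeros")) {
  mask <- match.arg(mask)
  masked_cell_stat(imputed, expected, observed, mask, function(a, b) {
    mean(abs(a - b))
  })
}

#' Imputed-expected correlation (CIEA / CIEZ)
#'
#' Pearson correlation between imputed and expected values per cell over the
#' masked entries, averaged across cells. Cells with zero variance in either
#' vector yield `NA` with a warning and are dropped from the average.
#'
#' @inheritParams abs_error
#' @return list with `mean`, `se` and `per_cell` tibble.
#' @export
imputation_cor <- function(imputed, expected, observed = NULL,
                           mask = c("all_observed", "observed_zeros")) {
  mask <- match.arg(mask)
  masked_cell_stat(imputed, expected, observed, mask, function(a, b) {
    if (length(a) < 2 || stats::sd(a) == 0 || stats::sd(b) == 0) {
      warning("zero variance in masked entries; correlation undefined")
      return(NA_real_)
    }
    stats::cor(a, b)
  })
}

masked_cell_stat <- function(imputed, expected, observed, mask, f) {
  if (is.matrix(imputed)) imputed <- list(imputed)
  if (is.matrix(expected)) expected <- list(expected)
  if (is.matrix(observed)) observed <- list(observed)
  if (length(imputed) != length(expected)) stop("imputed/expected length mismatch")
  if (mask == "observed_zeros" && is.null(observed)) {
    stop("observed matrices required for the observed-zeros mask")
  }
  vals <- vapply(seq_along(imputed), function(k) {
    im <- unclass(as.matrix(imputed[[k]]))
    ex <- unclass(as.matrix(expected[[k]]))
    sel <- upper.tri(im)
    if (mask == "observed_zeros") {
      sel <- sel & unclass(as.matrix(observed[[k]])) == 0
    }
    if (!any(sel)) stop("empty mask for cell ", k)
    f(im[sel], ex[sel])
  }, numeric(1))
  list(
    mean = mean(vals, na.rm = TRUE),
    se = stats::sd(vals, na.rm = TRUE) / sqrt(sum(!is.na(vals))),
    per_cell = tibble::tibble(cell = seq_along(vals), value = vals)
  )
}

#' Collect per-(cell, pair) scores and labels for observed zeros
#'
#' Helper assembling the ROC inputs: for every cell and pair `i < j` with an
#' observed zero, the discrimination score (posterior \eqn{\hat\pi} for the
#' model, negative smoothed value for the baselines) and the true label
#' (structural zero vs dropout).
#'
#' @param group a [schic_group()].
#' @param truth `sim_truth` from [simulate_schic()].
#' @param score_matrices either one matrix (pair-level score shared by all
#'   cells, e.g. \eqn{\hat\pi}) or a per-cell list (e.g. negated smoothed
#'   matrices).
#' @return tibble with columns `cell`, `idx`, `i`, `j`, `score`, `is_sz`.
#' @export
zero_scores <- function(group, truth, score_matrices) {
  if (is.matrix(score_matrices)) {
    score_matrices <- rep(list(score_matrices), length(group$cells))
  }
  pairs <- upper_pairs(group$n_bins)
  purrr::map_dfr(seq_along(group$cells), function(k) {
    obs <- vectorize_upper(unclass(group$cells[[k]]))
    sz <- vectorize_upper(truth$sz_mask[[k]]) > 0
    sc <- vectorize_upper(unclass(as.matrix(score_matrices[[k]])))
    keep <- obs == 0
    dplyr::mutate(pairs[keep, ],
      cell = k, score = sc[keep],
      is_sz = sz[keep], .before = 1
    )
  })
}

#' ROC curve and AUC for structural-zero discrimination
#'
#' Sweeps every distinct score threshold (equal scores collapse to one
#' operating point), calling a zero structural when its score is strictly
#' above the threshold. Sensitivity is PTSZ; 1 - specificity is the fraction
#' of true dropouts mis-called. AUC is the trapezoid-rule area, equal to the
#' Mann-Whitney probability with ties counted half.
#'
#' @param score numeric score per observed zero (higher = more structural).
#' @param is_sz logical true labels.
#' @return list of class `schic_roc`: `roc` tibble (`threshold`,
#'   `sensitivity`, `fpr`, `ptdo`) and scalar `auc`.
#' @export
roc_auc <- function(score, is_sz) {
  is_sz <- as.logical(is_sz)
  if (length(score) != length(is_sz)) stop("score/label length mismatch")
  n_sz <- sum(is_sz)
  n_do <- sum(!is_sz)
  if (n_sz == 0 || n_do == 0) stop("degenerate truth: need both classes")
  thr <- c(sort(unique(score), decreasing = TRUE), -Inf)
  sens <- c(0, vapply(thr, function(t) sum(score > t & is_sz) / n_sz, numeric(1)))
  fpr <- c(0, vapply(thr, function(t) sum(score > t & !is_sz) / n_do, numeric(1)))
  roc <- tibble::tibble(
    threshold = c(Inf, thr),
    sensitivity = sens,
    fpr = fpr,
    ptdo = 1 - fpr
  )
  auc <- sum(diff(roc$fpr) * (utils::head(roc$sensitivity, -1) +
    utils::tail(roc$sensitivity, -1)) / 2)
  structure(list(roc = roc, auc = auc), class = "schic_roc")
}

#' @export
print.schic_roc <- function(x, ...) {
  cat("<schic_roc> ", nrow(x$roc), " operating points, AUC = ",
    format(x$auc, digits = 4), "\n",
    sep = ""
  )
  invisible(x)
}

#' Calibrate the call threshold to a target sensitivity
#'
#' Finds the operating point with the smallest sensitivity at or above the
#' target PTSZ (the fixed-sensitivity comparison used to rank methods) and
#' reports its specificity.
#'
#' @param score,is_sz as in [roc_auc()].
#' @param target_ptsz target sensitivity (default 0.95).
#' @return one-row tibble: `threshold`, `ptsz`, `ptdo`.
#' @export
calibrate_threshold_at_ptsz <- function(score, is_sz, target_ptsz = 0.95) {
  r <- roc_auc(score, is_sz)$roc
  ok <- r[r$sensitivity >= target_ptsz, ]
  if (nrow(ok) == 0) stop("target PTSZ ", target_ptsz, " unreachable")
  best <- ok[which.min(ok$sensitivity), ]
  tibble::tibble(
    threshold = best$threshold,
    ptsz = best$sensitivity,
    ptdo = best$ptdo
  )
}

#' Full evaluation report for one or several methods
#'
#' Applies the complete metric suite (PTSZ/PTDO at each method's native call
#' rule, calibrated PTDO at the target PTSZ, AUC, AEOA/AEOZ, CIEA/CIEZ) to
#' imputation results against the simulation truth.
#'
#' @param sim a `schic_sim` from [simulate_schic()].
#' @param methods named list; each element is a list with `imputed` (per-cell
#'   matrices), `calls` (per-cell structural-zero call masks) and `scores`
#'   (one pair-level matrix or a per-cell list, higher = more structural).
#' @param target_ptsz sensitivity at which the calibrated comparison is made.
#' @return tibble with one row per method.
#' @export
evaluate_methods <- function(sim, methods, target_ptsz = 0.95) {
  group <- sim$group
  truth <- sim$truth
  obs <- lapply(group$cells, unclass)
  purrr::map_dfr(names(methods), function(nm) {
    m <- methods[[nm]]
    zs <- zero_scores(group, truth, m$scores)
    ra <- roc_auc(zs$score, zs$is_sz)
    cal <- calibrate_threshold_at_ptsz(zs$score, zs$is_sz, target_ptsz)
    errs <- list(
      aeoa = abs_error(m$imputed, truth$expected, obs, "all_observed"),
      aeoz = abs_error(m$imputed, truth$expected, obs, "observed_zeros"),
      ciea = imputation_cor(m$imputed, truth$expected, obs, "all_observed"),
      ciez = imputation_cor(m$imputed, truth$expected, obs, "observed_zeros")
    )
    tibble::tibble(
      method = nm,
      ptsz = ptsz(truth$sz_mask, m$calls),
      ptdo = ptdo(truth$do_mask, m$calls),
      ptdo_at_target = cal$ptdo,
      auc = ra$auc,
      aeoa = errs$aeoa$mean, aeoa_se = errs$aeoa$se,
      aeoz = errs$aeoz$mean, aeoz_se = errs$aeoz$se,
      ciea = errs$ciea$mean, ciea_se = errs$ciea$se,
      ciez = errs$ciez$mean, ciez_se = errs$ciez$se
    )
  })
}

#' Expected-versus-imputed scatter data (SEVI / SOVI)
#'
#' Long tibble of per-entry values for the two diagnostic scatterplots:
#' expected-versus-imputed on simulated data (SEVI, observed zeros flagged)
#' or observed-versus-imputed on any data (SOVI, nonzero entries only).
#'
#' @param imputed per-cell list of imputed matrices.
#' @param reference per-cell list of expected (`SEVI`) or observed (`SOVI`)
#'   matrices.
#' @param observed per-cell observed matrices, used to flag observed zeros.
#' @return tibble with `cell`, `i`, `j`, `reference`, `imputed`,
#'   `observed_zero`.
#' @export
sevi_data <- function(imputed, reference, observed) {
  n <- nrow(as.matrix(imputed[[1]]))
  pairs <- upper_pairs(n)
  purrr::map_dfr(seq_along(imputed), function(k) {
    dplyr::mutate(pairs,
      cell = k,
      reference = vectorize_upper(unclass(as.matrix(reference[[k]])))[idx],
      imputed = vectorize_upper(unclass(as.matrix(imputed[[k]])))[idx],
      observed_zero =
        vectorize_upper(unclass(as.matrix(observed[[k]])))[idx] == 0
    )
  })
}
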