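FINAL_COVARS <- c("age", "sex", "edu", "cpd", "hm")

check_records <- function(records, n) {
  miss <- setdiff(FINAL_COVARS, names(records))
  if (length(miss) > 0)
    stop("records missing covariate column(s): ",
         paste(miss, collapse = ", "))
  if (nrow(records) != n)
    stop("records rows (", nrow(records), ") do not match outcome (", n, ")")
  X <- as.matrix(records[, FINAL_COVARS])
  storage.mode(X) <- "double"
  if (anyNA(X) || any(!is.finite(X))) stop("non-finite covariate values")
  X
}

#' Final covariate-adjusted Cox model
#'
#' Fits the prediction model
#' `h(X, t) = h0(t) exp(indexP bP + indexR bR + age bA + sex bS + edu bE +
#' cpd bC + hm bH)` with the seven covariates assembled in this fixed
#' order.
#'
#' @param indices Data frame with `indexP`, `indexR` (from
#'   [composite_indices()]).
#' @param records Data frame with `age`, `sex`, `edu`, `cpd`, `hm`.
#' @param outcome A [surv_outcome()]; fewer than 8 events triggers a
#'   warning.
#' @inheritParams fit_cox
#' @return A [fit_cox()] result over the 7-column design.
#' @export
fit_final_model <- function(indices, records, outcome,
                            ties = c("breslow", "efron")) {
  outcome <- as_surv_outcome(outcome)
  X <- cbind(indexP = indices$indexP, indexR = indices$indexR,
             check_records(records, outcome$n))
  if (outcome$n_events < 8)
    warning("fewer than 8 events (", outcome$n_events,
            "); final-model estimates may be unstable")
  fit_cox(outcome, X, ties = match.arg(ties))
}

#' ROC analysis at a follow-up cut-off
#'
#' Subjects relapsing on or before `cutoff_days` (event = 1, duration <=
#' cutoff) are labeled positive; subjects observed beyond the cut-off
#' (duration > cutoff) negative. Subjects censored at or before the
#' cut-off carry no label and are excluded with a message. The curve sweeps
#' all distinct score thresholds; the AUC is computed by the Mann-Whitney
#' rank identity, which equals the trapezoidal area under that curve and
#' gives tied scores exactly 1/2 per pair.
#'
#' @param scores Numeric risk score per subject (higher = earlier relapse
#'   predicted).
#' @param outcome A [surv_outcome()].
#' @param cutoff_days Positive follow-up cut-off (e.g. 30, 90, 168).
#' @return Object of class `roc_result`: `fpr`, `tpr`, `thresholds`,
#'   `auc`, `n_pos`, `n_neg`, `n_excluded`, `cutoff_days`.
#' @export
roc_at_cutoff <- function(scores, outcome, cutoff_days) {
  outcome <- as_surv_outcome(outcome)
  if (length(scores) != outcome$n)
    stop("scores length does not match outcome")
  if (cutoff_days <= 0) stop("cutoff must be positive")
  pos <- outcome$events == 1L & outcome$durations <= cutoff_days
  neg <- outcome$durations > cutoff_days
  excl <- outcome$events == 0L & outcome$durations <= cutoff_days
  if (sum(excl) > 0)
    message(sum(excl), " subject(s) censored before the cut-off excluded",
            " from ROC labels")
  if (sum(pos) == 0 || sum(neg) == 0)
    stop("single-class labels at cutoff ", cutoff_days,
         " (", sum(pos), " positive, ", sum(neg), " negative)")
  s <- scores[!excl]
  y <- pos[!excl]
  thr <- c(Inf, sort(unique(s), decreasing = TRUE))
  tpr <- vapply(thr, function(t) mean(s[y] >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(s[!y] >= t), numeric(1))
  # Mann-Whitney rank identity: equal to the trapezoidal area under the
  # empirical ROC, with tied scores contributing exactly 1/2 per pair
  np <- sum(y)
  nn <- sum(!y)
  auc <- (sum(rank(s)[y]) - np * (np + 1) / 2) / (np * nn)
  structure(list(fpr = fpr, tpr = tpr, thresholds = thr, auc = auc,
                 n_pos = sum(pos), n_neg = sum(neg),
                 n_excluded = sum(excl), cutoff_days = cutoff_days),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> cutoff %g d | AUC %.4f | %d pos / %d neg",
              x$cutoff_days, x$auc, x$n_pos, x$n_neg),
      if (x$n_excluded > 0) sprintf("| %d excluded", x$n_excluded), "\n")
  invisible(x)
}

#' Nested leave-one-out cross-validation of the prediction pipeline
#'
#' For each subject in turn: the voxel-wise Cox screen, the p < alpha
#' thresholding into protective/risk masks, the composite indices and the
#' final covariate-adjusted Cox model are all recomputed on the remaining
#' n - 1 subjects; the held-out subject is then scored by that fold's
#' linear predictor at their own indices and covariates. The n out-of-fold
#' scores are evaluated by [roc_at_cutoff()]. Feature selection never sees
#' the held-out subject, so the evaluation is unbiased by selection.
#'
#' A fold whose masks are both empty falls back to a covariates-only model
#' and is flagged in `cov_only`.
#'
#' @param fc_cohort Subjects x voxels Fisher-z matrix.
#' @param records Data frame with `age`, `sex`, `edu`, `cpd`, `hm` (and
#'   optionally `subject_id`).
#' @param outcome A [surv_outcome()]; every training fold needs >= 2
#'   events.
#' @param alpha Voxel-screening threshold (default 0.001).
#' @param cutoff_days ROC follow-up cut-off (default 168).
#' @param return_masks Keep the per-fold circuit masks (voxels x folds
#'   logical matrices); needed for heat maps, costs memory.
#' @inheritParams fit_cox
#' @return Object of class `cv_result`: `scores`, `index_p`, `index_r`
#'   (per-subject out-of-fold values), `n_protective`/`n_risk` per fold,
#'   `cov_only` and `fit_ok` flags, `fold_beta` (coefficients x folds, NA
#'   where a column was absent), optional `prot_masks`/`risk_masks`, `roc`,
#'   `auc`, `alpha`, `cutoff_days`.
#' @export
loocv <- function(fc_cohort, records, outcome, alpha = 0.001,
                  cutoff_days = 168, ties = c("breslow", "efron"),
                  return_masks = TRUE, tol = 1e-8, max_iter = 100L,
                  beta_cap = 50) {
  outcome <- as_surv_outcome(outcome)
  ties <- match.arg(ties)
  Z <- as.matrix(fc_cohort)
  storage.mode(Z) <- "double"
  if (outcome$n < 10) stop("need at least 10 subjects for LOOCV")
  if (nrow(Z) != outcome$n) stop("FC rows do not match outcome")
  C <- check_records(records, outcome$n)
  res <- cpp_loocv(Z, C, outcome$durations, outcome$events, alpha,
                   if (ties == "breslow") 0L else 1L, tol,
                   as.integer(max_iter), beta_cap, return_masks)
  rownames(res$fold_beta) <- c("indexP", "indexR", FINAL_COVARS)
  if (any(res$cov_only == 1L))
    message(sum(res$cov_only), " fold(s) had empty masks; scored from ",
            "covariates only")
  roc <- roc_at_cutoff(res$scores, outcome, cutoff_days)
  structure(list(scores = res$scores, index_p = res$index_p,
                 index_r = res$index_r, n_protective = res$n_protective,
                 n_risk = res$n_risk, cov_only = res$cov_only == 1L,
                 fit_ok = res$fit_ok == 1L, fold_beta = res$fold_beta,
                 prot_masks = res$prot_mask, risk_masks = res$risk_mask,
                 roc = roc, auc = roc$auc, alpha = alpha,
                 cutoff_days = cutoff_days, ties = ties),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf(
    "<cv_result> n = %d folds | alpha %g | cutoff %g d | AUC %.4f\n",
    length(x$scores), x$alpha, x$cutoff_days, x$auc))
  cat(sprintf("  voxels/fold: protective %.1f, risk %.1f (means)\n",
              mean(x$n_protective), mean(x$n_risk)))
  invisible(x)
}

#' Recompute one leave-one-out fold with the R-level building blocks
#'
#' Runs a single fold of the nested loop -- screening, thresholding,
#' composite indices, final model -- through [voxelwise_cox()],
#' [threshold_maps()], [composite_indices()] and [fit_final_model()],
#' independently of the optimized all-in-one loop. Used to audit the fast
#' path and the leakage guarantee.
#'
#' @inheritParams loocv
#' @param leave_out Index of the held-out subject.
#' @return List with `masks`, `fit`, `indices` (training + held-out),
#'   `score` for the held-out subject.
#' @export
loocv_fold <- function(fc_cohort, records, outcome, leave_out,
                       alpha = 0.001, ties = c("breslow", "efron")) {
  outcome <- as_surv_outcome(outcome)
  ties <- match.arg(ties)
  Z <- as.matrix(fc_cohort)
  tr <- setdiff(seq_len(outcome$n), leave_out)
  out_tr <- surv_outcome(outcome$durations[tr], outcome$events[tr])
  stats <- voxelwise_cox(Z[tr, , drop = FALSE], out_tr, ties = ties)
  masks <- threshold_maps(stats, alpha)
  idx <- suppressWarnings(composite_indices(Z, masks))
  C <- check_records(records, outcome$n)
  design <- cbind(indexP = idx$indexP, indexR = idx$indexR, C)
  use <- c(any(masks$protective), any(masks$risk), rep(TRUE, ncol(C)))
  keep <- use & apply(design[tr, , drop = FALSE], 2, sd) > 1e-10
  fit <- suppressWarnings(
    fit_cox(out_tr, design[tr, keep, drop = FALSE], ties = ties))
  mu <- colMeans(design[tr, keep, drop = FALSE])
  score <- sum((design[leave_out, keep] - mu) * fit$coefficients)
  list(masks = masks, fit = fit, indices = idx, score = score)
}

#' Permutation-based empirical null for the cross-validated AUC
#'
#' Shuffles the (duration, event) pairs across subjects and re-runs the
#' entire nested leave-one-out analysis -- voxel screening included -- for
#' each permutation, recording the permuted AUC at the same cut-off. The
#' p-value is the add-one rank estimate
#' `p = (1 + #\{null >= observed\}) / (1 + n_perm)`, which can never
#' return 0. A `"reuse"` mode keeps the observed out-of-fold scores and
#' only permutes the ROC labels; it skips re-screening and is
#' anti-conservative -- use it for exploration only.
#'
#' @inheritParams loocv
#' @param n_perm Number of permutations (>= 100 recommended for
#'   reporting).
#' @param rng_seed Integer seed; identical seeds give bit-identical
#'   results.
#' @param mode `"full"` (faithful, default) or `"reuse"`
#'   (anti-conservative fast mode).
#' @param max_resample Cap on additional draws when a permutation fails.
#' @return Object of class `perm_test`: `observed_auc`, `null_aucs`,
#'   `p_value`, `n_perm`, `n_failed`, `cutoff_days`, `mode`, `rng_seed`.
#' @export
permutation_test <- function(fc_cohort, records, outcome, alpha = 0.001,
                             cutoff_days = 168, n_perm = 1000,
                             rng_seed = 1, ties = c("breslow", "efron"),
                             mode = c("full", "reuse"),
                             max_resample = 10 * n_perm) {
  outcome <- as_surv_outcome(outcome)
  ties <- match.arg(ties)
  mode <- match.arg(mode)
  Z <- as.matrix(fc_cohort)
  storage.mode(Z) <- "double"
  C <- check_records(records, outcome$n)
  tiescode <- if (ties == "breslow") 0L else 1L

  obs <- loocv(Z, records, outcome, alpha = alpha,
               cutoff_days = cutoff_days, ties = ties,
               return_masks = FALSE)
  n <- outcome$n
  set.seed(rng_seed)
  null_aucs <- numeric(n_perm)
  n_failed <- 0L
  done <- 0L
  draws <- 0L
  while (done < n_perm) {
    if (draws > n_perm + max_resample)
      stop("too many failed permutations (", n_failed, ")")
    perm <- sample.int(n)
    draws <- draws + 1L
    auc <- tryCatch({
      po <- surv_outcome(outcome$durations[perm], outcome$events[perm])
      if (mode == "full") {
        r <- cpp_loocv(Z, C, po$durations, po$events, alpha, tiescode,
                       1e-8, 100L, 50, FALSE)
        suppressMessages(roc_at_cutoff(r$scores, po, cutoff_days)$auc)
      } else {
        suppressMessages(roc_at_cutoff(obs$scores, po, cutoff_days)$auc)
      }
    }, error = function(e) NA_real_)
    if (is.na(auc)) {
      n_failed <- n_failed + 1L
    } else {
      done <- done + 1L
      null_aucs[done] <- auc
    }
  }
  p <- (1 + sum(null_aucs >= obs$auc)) / (1 + n_perm)
  structure(list(observed_auc = obs$auc, null_aucs = null_aucs,
                 p_value = p, n_perm = n_perm, n_failed = n_failed,
                 cutoff_days = cutoff_days, alpha = alpha, mode = mode,
                 rng_seed = rng_seed, scores = obs$scores),
            class = "perm_test")
}

#' @export
print.perm_test <- function(x, ...) {
  cat(sprintf(
    "<perm_test> AUC %.4f | p = %.4g (%d permutations, %s mode)\n",
    x$observed_auc, x$p_value, x$n_perm, x$mode))
  invisible(x)
}
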