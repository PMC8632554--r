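fake_records <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(age = runif(n, 25, 60), sex = rbinom(n, 1, 0.3),
             edu = runif(n, 8, 18), cpd = runif(n, 0, 30),
             hm = runif(n, 0.03, 0.15))
}

test_that("ROC at a cut-off matches its documented edge cases", {
  out <- surv_outcome(c(10, 20, 200, 200), c(1, 1, 0, 0))
  expect_equal(roc_at_cutoff(c(3, 2, 1, 0), out, 30)$auc, 1.0)
  expect_equal(roc_at_cutoff(c(0, 1, 2, 3), out, 30)$auc, 0.0)
  expect_equal(roc_at_cutoff(c(1, 1, 1, 1), out, 30)$auc, 0.5)
  # censored before the cut-off: excluded with a count
  out2 <- surv_outcome(c(10, 20, 25, 200), c(1, 1, 0, 0))
  expect_message(r <- roc_at_cutoff(c(3, 2, 1, 0), out2, 30), "excluded")
  expect_equal(r$n_excluded, 1L)
  expect_equal(r$n_pos + r$n_neg, 3L)
  expect_error(roc_at_cutoff(1:3, surv_outcome(c(1, 2, 3), c(1, 1, 1)), 200),
               "single-class")
})

test_that("trapezoidal AUC equals exhaustive pair counting on small cohorts", {
  set.seed(31)
  for (rep in 1:50) {
    n <- sample(4:12, 1)
    dur <- sample(c(5, 20, 60, 200), n, replace = TRUE)
    ev <- rbinom(n, 1, 0.7)
    sc <- sample(seq(0, 2, 0.25), n, replace = TRUE)  # coarse: forces ties
    cutoff <- 90
    pos <- ev == 1 & dur <= cutoff
    neg <- dur > cutoff
    if (sum(pos) == 0 || sum(neg) == 0) next
    keep <- pos | neg
    r <- suppressMessages(roc_at_cutoff(sc, surv_outcome(dur, ev), cutoff))
    expect_identical(r$auc, bf_auc(sc[keep], pos[keep]))
  }
})

test_that("final model recovers a pure indexR effect with quiet covariates", {
  set.seed(17)
  hits_r <- 0; quiet <- 0; reps <- 30
  for (i in 1:reps) {
    n <- 80
    u_r <- rnorm(n)
    rec <- fake_records(n, seed = 1000 + i)
    idx <- data.frame(indexP = rnorm(n), indexR = u_r)
    raw <- rexp(n, 0.01 * exp(0.9 * u_r))
    out <- surv_outcome(pmin(raw, 168), as.integer(raw <= 168))
    fit <- fit_final_model(idx, rec, out)
    z <- fit$z_wald
    hits_r <- hits_r + (z["indexR"] > 2)
    quiet <- quiet + sum(abs(z[c("age", "sex", "edu", "cpd", "hm")]) < 2)
  }
  expect_gte(hits_r / reps, 0.9)
  expect_gte(quiet / (5 * reps), 0.9)  # null covariates stay quiet
})

test_that("final model errors on duplicated indices and fixes column order", {
  n <- 40
  rec <- fake_records(n, seed = 2)
  u <- rnorm(n)
  out <- surv_outcome(pmin(rexp(n, 0.01 * exp(0.5 * u)), 168),
                      rep(1L, n))
  idx <- data.frame(indexP = u, indexR = u)
  expect_error(fit_final_model(idx, rec, out), "degenerate-covariate")
  idx2 <- data.frame(indexP = rnorm(n), indexR = u)
  fit <- fit_final_model(idx2, rec, out)
  expect_identical(fit$var_names,
                   c("indexP", "indexR", "age", "sex", "edu", "cpd", "hm"))
})

test_that("the optimized LOOCV loop agrees with the R building blocks", {
  ch <- make_cohort(n = 24, grid = c(8, 8, 8), seed = 12)
  cv <- suppressMessages(loocv(ch$fc, ch$records, ch$outcome, alpha = 0.01,
                               cutoff_days = median(ch$outcome$durations)))
  for (i in c(1, 9, 24)) {
    fold <- suppressMessages(
      loocv_fold(ch$fc, ch$records, ch$outcome, i, alpha = 0.01))
    expect_identical(unname(cv$prot_masks[, i]), unname(fold$masks$protective))
    expect_identical(unname(cv$risk_masks[, i]), unname(fold$masks$risk))
    expect_equal(cv$scores[i], fold$score, tolerance = 1e-8)
    expect_equal(cv$index_p[i], fold$indices$indexP[i], tolerance = 1e-12)
  }
})

test_that("the held-out subject cannot leak into its own fold", {
  ch <- make_cohort(n = 20, grid = c(8, 8, 8), seed = 4)
  cv <- suppressMessages(loocv(ch$fc, ch$records, ch$outcome, alpha = 0.01,
                               cutoff_days = median(ch$outcome$durations)))
  for (i in c(2, 10, 19)) {
    fc2 <- ch$fc
    fc2[i, ] <- 0  # erase the held-out subject's map entirely
    cv2 <- suppressMessages(loocv(fc2, ch$records, ch$outcome, alpha = 0.01,
                                  cutoff_days = median(ch$outcome$durations)))
    expect_identical(cv$prot_masks[, i], cv2$prot_masks[, i])
    expect_identical(cv$risk_masks[, i], cv2$risk_masks[, i])
    expect_identical(cv$fold_beta[, i], cv2$fold_beta[, i])
  }
})

test_that("LOOCV validates fold event counts and duplication does not break it", {
  ch <- make_cohort(n = 16, grid = c(8, 8, 8), seed = 6)
  few <- ch$outcome
  few$events[] <- 0L
  few$events[1:2] <- 1L
  few$n_events <- 2L
  expect_error(
    suppressMessages(loocv(ch$fc, ch$records, few, cutoff_days = 100)),
    "fewer than 2 events")
  ch2 <- make_cohort(n = 30, grid = c(8, 8, 8), seed = 13)
  cut <- median(ch2$outcome$durations)
  cv1 <- suppressMessages(loocv(ch2$fc, ch2$records, ch2$outcome,
                                cutoff_days = cut, return_masks = FALSE))
  dup <- c(seq_len(30), seq_len(30))
  out_d <- surv_outcome(ch2$outcome$durations[dup], ch2$outcome$events[dup])
  cv2 <- suppressMessages(loocv(ch2$fc[dup, ], ch2$records[dup, ], out_d,
                                cutoff_days = cut, return_masks = FALSE))
  expect_gte(cv2$auc, cv1$auc - 0.05)
})

test_that("permutation p-values follow the add-one rank formula and the seed", {
  ch <- make_cohort(n = 20, grid = c(8, 8, 8), seed = 9)
  cut <- median(ch$outcome$durations)
  pt <- suppressMessages(
    permutation_test(ch$fc, ch$records, ch$outcome, alpha = 0.01,
                     cutoff_days = cut, n_perm = 30, rng_seed = 42))
  expect_equal(pt$p_value,
               (1 + sum(pt$null_aucs >= pt$observed_auc)) / (1 + 30))
  expect_gt(pt$p_value, 0)
  expect_lte(pt$p_value, 1)
  pt2 <- suppressMessages(
    permutation_test(ch$fc, ch$records, ch$outcome, alpha = 0.01,
                     cutoff_days = cut, n_perm = 30, rng_seed = 42))
  expect_identical(pt$null_aucs, pt2$null_aucs)
  expect_identical(pt$p_value, pt2$p_value)
  # reuse mode shares the observed scores but still permutes labels
  ptr <- suppressMessages(
    permutation_test(ch$fc, ch$records, ch$outcome, alpha = 0.01,
                     cutoff_days = cut, n_perm = 30, rng_seed = 42,
                     mode = "reuse"))
  expect_identical(ptr$observed_auc, pt$observed_auc)
})
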