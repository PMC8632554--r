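fake_masks <- function(pm, rm_) {
  list(prot_masks = pm, risk_masks = rm_)
}

test_that("circuit heat map counts fold inclusion frequencies", {
  V <- 5; n <- 43
  pm <- matrix(FALSE, V, n)
  rm_ <- matrix(FALSE, V, n)
  pm[1, ] <- TRUE            # in every fold
  pm[2, 1:37] <- TRUE        # 37 of 43
  rm_[3, seq(2, n, 2)] <- TRUE
  hm <- circuit_heatmap(fake_masks(pm, rm_))
  expect_equal(hm$protective_freq[1], 1.0)
  expect_equal(hm$protective_freq[2], 37 / 43)
  expect_equal(hm$protective_freq[4], 0.0)
  expect_equal(hm$n_folds, n)
  expect_error(circuit_heatmap(fake_masks(pm, rm_[1:3, ])), "match")
})

test_that("group masks use a strict frequency threshold and are monotone", {
  V <- 4
  pm <- matrix(FALSE, V, 100)
  pm[1, 1:86] <- TRUE   # 0.86 > 0.85 -> in
  pm[2, 1:85] <- TRUE   # 0.85 exactly -> out
  rm_ <- matrix(FALSE, V, 100)
  hm <- circuit_heatmap(fake_masks(pm, rm_))
  gm <- suppressWarnings(group_masks(hm, 0.85))
  expect_true(gm$protective[1])
  expect_false(gm$protective[2])
  # raising the threshold never adds voxels
  for (f in c(0.5, 0.7, 0.9)) {
    lo <- suppressWarnings(group_masks(hm, f))
    hi <- suppressWarnings(group_masks(hm, min(f + 0.2, 1)))
    expect_true(all(which(hi$protective) %in% which(lo$protective)))
  }
})

test_that("post-hoc indices are means over the group masks", {
  masks <- structure(list(protective = c(TRUE, FALSE, FALSE),
                          risk = c(FALSE, TRUE, TRUE), alpha = 0.85),
                     class = "circuit_masks")
  fc <- rbind(c(0.4, 0.2, 0.6), c(1, 1, 1))
  ph <- posthoc_indices(fc, masks)
  expect_equal(ph$idxP_ph, c(0.4, 1))    # single voxel: the value itself
  expect_equal(ph$idxR_ph, c(0.4, 1))    # uniform rows: the constant
  # duplicating mask voxels with identical values keeps the mean
  masks2 <- structure(list(protective = c(TRUE, TRUE, FALSE, FALSE),
                           risk = c(FALSE, FALSE, TRUE, TRUE), alpha = 0.85),
                      class = "circuit_masks")
  fc2 <- cbind(fc[, 1], fc[, 1], fc[, 2:3])
  expect_equal(posthoc_indices(fc2, masks2)$idxP_ph, ph$idxP_ph)
  empty <- structure(list(protective = rep(FALSE, 3), risk = masks$risk,
                          alpha = 0.85), class = "circuit_masks")
  expect_error(posthoc_indices(fc, empty), "empty")
})

test_that("the 3-SD rule excludes exactly the flagged subjects in one pass", {
  base <- data.frame(subject_id = as.character(1:43),
                     idxP_ph = rep(c(-0.1, 0, 0.1), length.out = 43),
                     idxR_ph = rep(c(0.2, 0.3), length.out = 43),
                     included = TRUE)
  class(base) <- c("posthoc_indices", "data.frame")
  same <- base
  same$idxP_ph <- rep(0.5, 43)
  same$idxR_ph <- rep(0.5, 43)
  expect_true(all(exclude_outliers(same)$included))
  out <- base
  out$idxP_ph[7] <- mean(base$idxP_ph) + 4.5 * sd(base$idxP_ph)
  ex <- exclude_outliers(out)
  expect_false(ex$included[7])
  expect_equal(sum(ex$included), 42)
  expect_error(exclude_outliers(base[1:4, ]), "5 subjects")
})

test_that("protective-risk regression reports OLS slope and R-squared", {
  pts <- data.frame(subject_id = as.character(1:10),
                    idxP_ph = seq(0, 1, length.out = 10),
                    idxR_ph = 2 - 3 * seq(0, 1, length.out = 10),
                    included = TRUE)
  class(pts) <- c("posthoc_indices", "data.frame")
  pr <- suppressWarnings(pr_regression(pts))  # exact fit trips summary.lm
  expect_equal(pr$slope, -3, tolerance = 1e-10)
  expect_equal(pr$r_squared, 1, tolerance = 1e-10)
  # independence: R^2 small in most seeded runs, and symmetric under swap
  low <- 0
  for (s in 1:20) {
    set.seed(s)
    ind <- pts[rep(1, 200), ]
    ind$idxP_ph <- rnorm(200)
    ind$idxR_ph <- rnorm(200)
    ind$included <- TRUE
    class(ind) <- c("posthoc_indices", "data.frame")
    r2 <- pr_regression(ind)$r_squared
    low <- low + (r2 < 0.05)
    swap <- ind
    swap$idxP_ph <- ind$idxR_ph
    swap$idxR_ph <- ind$idxP_ph
    expect_equal(pr_regression(swap)$r_squared, r2, tolerance = 1e-12)
  }
  expect_gte(low / 20, 0.95)
})

test_that("elbow ratio decreases over k and drops hardest by the true k", {
  blobs <- simulate_blobs(15, rbind(c(0, 0), c(8, 0), c(0, 8), c(8, 8)),
                          sd = 0.4, rng_seed = 2)
  ec <- elbow_curve(blobs$points, k_range = 2:8, rng_seed = 2, restarts = 30)
  drops <- -diff(ec$ratio)
  expect_lte(which.max(drops) + 1, 4)  # largest marginal drop at k <= 4
  expect_lte(sum(diff(ec$ratio) > 1e-8), 1)  # near-monotone decrease
  expect_error(elbow_curve(blobs$points[1:5, ], k_range = 2:6), "smaller")
})

test_that("k-means subtyping recovers planted blobs deterministically", {
  two <- simulate_blobs(20, rbind(c(0, 0), c(10, 10)), sd = 0.5,
                        rng_seed = 3)
  st <- kmeans_subtypes(two$points, k = 2, rng_seed = 1, restarts = 20)
  expect_equal(adjusted_rand(st$labels, two$labels), 1)
  # canonical labels survive a permutation of point order
  perm <- sample(seq_len(40))
  st2 <- kmeans_subtypes(two$points[perm, ], k = 2, rng_seed = 1,
                         restarts = 20)
  expect_identical(st2$labels, st$labels[perm])
  # per-cluster median durations attach from the outcome
  out <- surv_outcome(c(rep(7, 20), rep(120, 20)), rep(1L, 40))
  st3 <- kmeans_subtypes(two$points, k = 2, rng_seed = 1, restarts = 20,
                         outcome = out)
  expect_equal(sort(st3$medians), c(7, 120))
  # reported statistics are invariant to relabeling clusters
  relab <- c(2, 1)[st3$labels]
  expect_equal(sort(tabulate(relab, 2)), sort(tabulate(st3$labels, 2)))
})

test_that("more restarts never worsen the best within-cluster distance", {
  blobs <- simulate_blobs(12, rbind(c(0, 0), c(4, 4), c(0, 5)), sd = 0.8,
                          rng_seed = 4)
  set.seed(10)
  w_few <- kmeans_subtypes(blobs$points, 3, rng_seed = 5, restarts = 2)$within
  w_many <- kmeans_subtypes(blobs$points, 3, rng_seed = 5,
                            restarts = 40)$within
  expect_lte(w_many, w_few + 1e-10)
})
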