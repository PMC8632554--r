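#' Cross-fold circuit inclusion heat map
#'
#' Binarizes every fold's protective and risk masks and stacks them: each
#' voxel's value is the fraction of leave-one-out folds in which it entered
#' that circuit.
#'
#' @param cv A `cv_result` from [loocv()] run with `return_masks = TRUE`,
#'   or a list with `prot_masks`/`risk_masks` voxels x folds logical
#'   matrices.
#' @return Object of class `circuit_heatmap`: `protective_freq`,
#'   `risk_freq` (per-voxel fractions in `[0, 1]`), `n_folds`.
#' @export
circuit_heatmap <- function(cv) {
  pm <- cv$prot_masks
  rm_ <- cv$risk_masks
  if (is.null(pm) || is.null(rm_))
    stop("per-fold masks absent; run loocv() with return_masks = TRUE")
  if (!identical(dim(pm), dim(rm_))) stop("mask grids do not match")
  if (ncol(pm) < 2) stop("need at least 2 folds")
  structure(list(protective_freq = rowMeans(pm), risk_freq = rowMeans(rm_),
                 n_folds = ncol(pm)),
            class = "circuit_heatmap")
}

#' Group-level circuit masks from the heat map
#'
#' A voxel joins the group-level mask when its inclusion frequency is
#' strictly greater than `min_fraction` (the ">85% of folds" rule).
#' Per-fold masks are disjoint, so the group masks cannot conflict.
#'
#' @param heatmap A [circuit_heatmap()].
#' @param min_fraction Frequency threshold in (0, 1]; strict inequality.
#' @return A `circuit_masks` object (see [threshold_maps()]).
#' @export
group_masks <- function(heatmap, min_fraction = 0.85) {
  stopifnot(inherits(heatmap, "circuit_heatmap"))
  if (!(min_fraction > 0 && min_fraction <= 1))
    stop("min_fraction must be in (0, 1]")
  prot <- heatmap$protective_freq > min_fraction
  risk <- heatmap$risk_freq > min_fraction
  if (!any(prot) && !any(risk))
    warning("empty group-level masks at threshold ", min_fraction)
  structure(list(protective = prot, risk = risk, alpha = min_fraction),
            class = "circuit_masks")
}

#' Post-hoc averaged circuit indices
#'
#' Per-subject mean (not sum) Fisher-z connectivity within the group-level
#' protective and risk circuits: `idxP_ph` and `idxR_ph`.
#'
#' @param fc_cohort Subjects x voxels Fisher-z matrix.
#' @param masks Group-level `circuit_masks` (both nonempty).
#' @param subject_ids Optional identifiers; defaults to row names or
#'   indices.
#' @return Object of class `posthoc_indices`: data frame with
#'   `subject_id`, `idxP_ph`, `idxR_ph`, `included` (all `TRUE` until
#'   [exclude_outliers()]).
#' @export
posthoc_indices <- function(fc_cohort, masks, subject_ids = NULL) {
  stopifnot(inherits(masks, "circuit_masks"))
  m <- as.matrix(fc_cohort)
  if (ncol(m) != length(masks$protective)) stop("voxel grid mismatch")
  if (!any(masks$protective) || !any(masks$risk))
    stop("cannot average over an empty group-level mask")
  if (is.null(subject_ids))
    subject_ids <- rownames(m) %||% as.character(seq_len(nrow(m)))
  out <- data.frame(
    subject_id = subject_ids,
    idxP_ph = rowMeans(m[, masks$protective, drop = FALSE]),
    idxR_ph = rowMeans(m[, masks$risk, drop = FALSE]),
    included = TRUE)
  class(out) <- c("posthoc_indices", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Flag outlying subjects on the post-hoc indices
#'
#' Single pass: mean and SD are computed on the full sample; a subject is
#' excluded when either index lies more than `n_sd` standard deviations
#' from its mean.
#'
#' @param indices A [posthoc_indices()] result (>= 5 subjects).
#' @param n_sd Exclusion radius in SD units (default 3).
#' @return The same object with `included` updated.
#' @export
exclude_outliers <- function(indices, n_sd = 3) {
  stopifnot(inherits(indices, "posthoc_indices"))
  if (nrow(indices) < 5) stop("need at least 5 subjects")
  out_of <- function(v) {
    s <- sd(v)
    if (s == 0) rep(FALSE, length(v)) else abs(v - mean(v)) > n_sd * s
  }
  indices$included <- !(out_of(indices$idxP_ph) | out_of(indices$idxR_ph))
  indices
}

#' Protective-risk linear regression
#'
#' Ordinary least squares of `idxR_ph` on `idxP_ph` over the included
#' subjects; reports slope, intercept, R-squared (= squared Pearson
#' correlation) and the slope's t-test p-value.
#'
#' @param indices A [posthoc_indices()] result.
#' @return List with `slope`, `intercept`, `r_squared`, `p_value`, `n`.
#' @export
pr_regression <- function(indices) {
  stopifnot(inherits(indices, "posthoc_indices"))
  d <- indices[indices$included, ]
  if (nrow(d) < 3) stop("need at least 3 included subjects")
  if (sd(d$idxP_ph) == 0 || sd(d$idxR_ph) == 0)
    stop("zero variance on an index")
  fit <- lm(idxR_ph ~ idxP_ph, data = d)
  sm <- summary(fit)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r_squared = sm$r.squared,
       p_value = sm$coefficients["idxP_ph", "Pr(>|t|)"], n = nrow(d))
}

# k-means++ seeding: first center uniform, subsequent centers sampled with
# probability proportional to squared distance to the nearest chosen center.
kmeanspp_init <- function(points, k) {
  n <- nrow(points)
  centers <- matrix(NA_real_, k, ncol(points))
  centers[1, ] <- points[sample.int(n, 1), ]
  d2 <- colSums((t(points) - centers[1, ])^2)
  for (j in seq_len(k - 1)) {
    pick <- if (sum(d2) == 0) sample.int(n, 1)
    else sample.int(n, 1, prob = d2)
    centers[j + 1, ] <- points[pick, ]
    d2 <- pmin(d2, colSums((t(points) - centers[j + 1, ])^2))
  }
  centers
}

within_between <- function(points, labels, centers, squared = FALSE) {
  d <- sqrt(rowSums((points - centers[labels, , drop = FALSE])^2))
  if (squared) d <- d^2
  within <- sum(d)
  pairs <- utils::combn(nrow(centers), 2)
  db <- sqrt(colSums((centers[pairs[1, ], , drop = FALSE] -
                        centers[pairs[2, ], , drop = FALSE])^2))
  if (squared) db <- db^2
  list(within = within, between = sum(db))
}

best_kmeans <- function(points, k, restarts, squared = FALSE) {
  best <- NULL
  fails <- 0L
  r <- 0L
  while (r < restarts) {
    init <- kmeanspp_init(points, k)
    km <- tryCatch(
      suppressWarnings(kmeans(points, centers = init, iter.max = 100)),
      error = function(e) NULL)
    if (is.null(km) || length(unique(km$cluster)) < k) {
      fails <- fails + 1L
      if (fails > 50L + restarts) stop("persistent empty clusters at k = ", k)
      next
    }
    r <- r + 1L
    wb <- within_between(points, km$cluster, km$centers, squared)
    if (is.null(best) || wb$within < best$within) {
      best <- list(cluster = km$cluster, centers = km$centers,
                   within = wb$within, between = wb$between)
    }
  }
  best
}

#' Elbow curve for cluster-number selection
#'
#' For each candidate k, runs best-of-restarts k-means (k-means++ seeding)
#' and reports the ratio of the sum of within-cluster distances (each
#' point to its centroid) to the sum of between-cluster distances (all
#' unordered centroid pairs). Euclidean distances by default; squared
#' variants with `squared = TRUE`. The returned curve carries a knee
#' suggestion (largest second difference) as an attribute, but the pick is
#' left to visual inspection.
#'
#' @param points n x 2 (or n x d) numeric matrix.
#' @param k_range Candidate cluster counts (default 2..11); all must be
#'   < n.
#' @param rng_seed Integer seed for reproducible restarts.
#' @param restarts Restarts per k (default 100).
#' @param squared Use squared distances in both sums.
#' @return Data frame `k`, `ratio`, `within`, `between`, with attribute
#'   `knee`.
#' @export
elbow_curve <- function(points, k_range = 2:11, rng_seed = 1,
                        restarts = 100, squared = FALSE) {
  points <- as.matrix(points)
  if (max(k_range) >= nrow(points)) stop("k must be smaller than n")
  degenerate <- all(apply(points, 2, sd) == 0)
  if (degenerate)
    warning("all points identical; within-cluster distance is 0 at every k")
  set.seed(rng_seed)
  rows <- lapply(k_range, function(k) {
    b <- best_kmeans(points, k, restarts, squared)
    data.frame(k = k, ratio = b$within / b$between, within = b$within,
               between = b$between)
  })
  out <- do.call(rbind, rows)
  if (nrow(out) >= 3) {
    d2 <- diff(diff(out$ratio))
    attr(out, "knee") <- out$k[which.max(d2) + 1L]
  }
  out
}

#' k-means disease subtyping in the (idxP_ph, idxR_ph) plane
#'
#' Best-of-restarts k-means with k-means++ seeding. Clusters are relabeled
#' canonically (descending centroid first coordinate, ties by the second)
#' so labels do not depend on restart order; per-cluster median follow-up
#' duration is attached when an outcome is supplied.
#'
#' @param points n x 2 numeric matrix (rows = included subjects).
#' @param k Number of clusters (>= 2, < n).
#' @param rng_seed Integer seed.
#' @param restarts Restarts (default 100).
#' @param outcome Optional [surv_outcome()] aligned with `points` rows.
#' @param squared Distance convention for the within sum used to pick the
#'   best restart.
#' @return Object of class `subtype_result`: `k`, `labels`, `centroids`,
#'   `within`, `between`, `medians` (median duration per cluster, or
#'   `NULL`).
#' @export
kmeans_subtypes <- function(points, k, rng_seed = 1, restarts = 100,
                            outcome = NULL, squared = FALSE) {
  points <- as.matrix(points)
  if (k < 2) stop("k must be >= 2")
  if (k >= nrow(points)) stop("k must be smaller than n")
  set.seed(rng_seed)
  b <- best_kmeans(points, k, restarts, squared)
  ord <- order(-b$centers[, 1], b$centers[, if (ncol(points) > 1) 2 else 1])
  relabel <- match(seq_len(k), ord)
  labels <- relabel[b$cluster]
  centroids <- b$centers[ord, , drop = FALSE]
  rownames(centroids) <- NULL
  medians <- NULL
  if (!is.null(outcome)) {
    outcome <- as_surv_outcome(outcome)
    if (outcome$n != nrow(points)) stop("outcome does not match points")
    medians <- vapply(seq_len(k), function(j)
      median(outcome$durations[labels == j]), numeric(1))
  }
  structure(list(k = k, labels = labels, centroids = centroids,
                 within = b$within, between = b$between,
                 medians = medians),
            class = "subtype_result")
}

#' @export
print.subtype_result <- function(x, ...) {
  cat("<subtype_result> k =", x$k, "| sizes:",
      paste(tabulate(x$labels, x$k), collapse = "/"))
  if (!is.null(x$medians))
    cat(" | median days:", paste(x$medians, collapse = "/"))
  cat("\n")
  invisible(x)
}
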