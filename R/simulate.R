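#' Configuration for the synthetic relapse cohort generator
#'
#' Defines the generative model the prediction pipeline assumes: two
#' disjoint planted voxel circuits whose subject loadings drive the hazard
#' log-linearly, exponential event times administratively censored, and
#' nuisance covariates with (by default) no effect. Defaults mirror the
#' study regime the package targets: 168-day follow-up, a protective and a
#' risk circuit of moderate size, and covariates drawn from plausible
#' clinical ranges.
#'
#' @param n_subjects Cohort size.
#' @param grid_shape Integer length-3 voxel grid (default 20 x 20 x 20);
#'   the brain mask is the central ellipsoid with semi-axes
#'   `grid_shape / 2 - 1`.
#' @param v_p,v_r Number of protective / risk circuit voxels (disjoint,
#'   sampled inside the mask).
#' @param loading Circuit signal amplitude `a`: in-circuit voxel z-values
#'   are `a * latent + noise`.
#' @param noise_sd Voxel noise SD `sigma`.
#' @param latent_cor Correlation `rho` between the protective and risk
#'   subject latents (default 0, keeping null-calibration checks exact).
#' @param b_p Hazard log-coefficient of the protective latent (<= 0).
#' @param b_r Hazard log-coefficient of the risk latent (>= 0).
#' @param h0 Baseline hazard per day (default 0.01: about 81% relapse by
#'   day 168 when `b_p = b_r = 0`).
#' @param censor_day Administrative censoring day (default 168).
#' @param covariate_effects Named numeric vector of hazard
#'   log-coefficients for `age, sex, edu, cpd, hm` (default all zero).
#' @param rng_seed Integer seed; the cohort is a deterministic function of
#'   the config.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 60, grid_shape = c(20, 20, 20),
                       v_p = 50, v_r = 50, loading = 1, noise_sd = 0.3,
                       latent_cor = 0, b_p = -0.7, b_r = 0.7, h0 = 0.01,
                       censor_day = 168,
                       covariate_effects = c(age = 0, sex = 0, edu = 0,
                                             cpd = 0, hm = 0),
                       rng_seed = 1) {
  if (censor_day <= 0) stop("censor_day must be positive")
  if (b_p > 0) stop("b_p must be <= 0 (protective)")
  if (b_r < 0) stop("b_r must be >= 0 (risk)")
  if (abs(latent_cor) >= 1) stop("latent_cor must be in (-1, 1)")
  cfg <- list(n_subjects = n_subjects, grid_shape = as.integer(grid_shape),
              v_p = v_p, v_r = v_r, loading = loading, noise_sd = noise_sd,
              latent_cor = latent_cor, b_p = b_p, b_r = b_r, h0 = h0,
              censor_day = censor_day,
              covariate_effects = covariate_effects, rng_seed = rng_seed)
  class(cfg) <- "sim_config"
  cfg
}

#' Central-ellipsoid brain mask for a grid
#'
#' @param grid_shape Integer length-3 grid dimensions.
#' @return Logical 3D array.
#' @export
ellipsoid_mask <- function(grid_shape) {
  ctr <- (grid_shape + 1) / 2
  r <- pmax(grid_shape / 2 - 1, 1)
  idx <- expand.grid(x = seq_len(grid_shape[1]), y = seq_len(grid_shape[2]),
                     z = seq_len(grid_shape[3]))
  inside <- ((idx$x - ctr[1]) / r[1])^2 + ((idx$y - ctr[2]) / r[2])^2 +
    ((idx$z - ctr[3]) / r[3])^2 <= 1
  array(inside, grid_shape)
}

#' Simulate a synthetic relapse cohort with planted circuits
#'
#' Per subject: bivariate-normal latents `(u_P, u_R)` with correlation
#' `rho`; Fisher-z voxel values `a u_P + eps` in the protective circuit,
#' `a u_R + eps` in the risk circuit and `eps ~ N(0, sigma^2)` elsewhere;
#' hazard `h0 exp(b_P u_P + b_R u_R + covariate effects)`; exponential raw
#' event time censored administratively at `censor_day`. Covariates are
#' drawn uniformly from plausible clinical ranges (age 25-60 y, sex
#' Bernoulli(0.12), education 8-18 y, 0-30 cigarettes/day, mean FD
#' 0.03-0.15 mm) and by default do not enter the hazard.
#'
#' @param config A [sim_config()].
#' @return Object of class `sim_cohort`: `fc` (subjects x in-mask voxels
#'   matrix), `records` (subject table), `outcome` ([surv_outcome()]),
#'   `mask` (logical 3D array), `truth` (latents, circuit voxel indices in
#'   in-mask order, true coefficients), `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$rng_seed)
  mask <- ellipsoid_mask(config$grid_shape)
  V <- sum(mask)
  if (config$v_p + config$v_r > V)
    stop("circuits (", config$v_p + config$v_r,
         " voxels) do not fit inside the mask (", V, ")")
  n <- config$n_subjects
  circ <- sample.int(V, config$v_p + config$v_r)
  prot <- sort(circ[seq_len(config$v_p)])
  risk <- sort(circ[config$v_p + seq_len(config$v_r)])

  rho <- config$latent_cor
  u_p <- rnorm(n)
  u_r <- rho * u_p + sqrt(1 - rho^2) * rnorm(n)

  fc <- matrix(rnorm(n * V, sd = config$noise_sd), n, V)
  fc[, prot] <- fc[, prot] + config$loading * u_p
  fc[, risk] <- fc[, risk] + config$loading * u_r

  records <- data.frame(
    subject_id = sprintf("S%03d", seq_len(n)),
    age = runif(n, 25, 60), sex = rbinom(n, 1, 0.12),
    edu = runif(n, 8, 18), cpd = runif(n, 0, 30),
    hm = runif(n, 0.03, 0.15))
  ce <- config$covariate_effects
  lin <- config$b_p * u_p + config$b_r * u_r +
    as.matrix(records[, names(ce)]) %*% ce
  hazard <- config$h0 * exp(drop(lin))
  raw <- rexp(n, rate = hazard)
  durations <- pmin(raw, config$censor_day)
  events <- as.integer(raw <= config$censor_day)
  records$duration <- durations
  records$event <- events
  rownames(fc) <- records$subject_id

  structure(list(fc = fc, records = records,
                 outcome = surv_outcome(durations, events), mask = mask,
                 truth = list(u_p = u_p, u_r = u_r, protective = prot,
                              risk = risk, b_p = config$b_p,
                              b_r = config$b_r),
                 config = config),
            class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat("<sim_cohort> n =", x$outcome$n, "| events =", x$outcome$n_events,
      "|", ncol(x$fc), "voxels | circuits", x$config$v_p, "+",
      x$config$v_r, "\n")
  invisible(x)
}

#' Simulate 4D BOLD data with known seed-voxel correlations
#'
#' Builds a band-limited Gaussian seed series `s(t)` and, per voxel with
#' target correlation `w`, the series `w s + sqrt(1 - w^2) e` with
#' independent unit-variance noise `e`, so the population seed
#' correlation equals the target. Exercises the connectivity and
#' preprocessing stack end to end.
#'
#' @param target_cc Numeric vector of target correlations in (-1, 1), one
#'   per in-mask voxel of `grid_shape`'s central ellipsoid.
#' @param n_frames Number of volumes T.
#' @param tr_seconds Repetition time.
#' @param grid_shape Grid for the volume (mask = central ellipsoid; its
#'   voxel count must match `length(target_cc)`).
#' @param seed_voxels Number of mask voxels forming the seed ROI (taken
#'   from the mask's first voxels; their series is the seed series plus
#'   tiny jitter).
#' @param low_hz,high_hz Seed-series band limits.
#' @param rng_seed Integer seed.
#' @return List with `bold` (a [bold4d()]), `roi` (a [seed_roi()]) and
#'   `seed_series`.
#' @export
simulate_bold <- function(target_cc, n_frames = 200, tr_seconds = 1.7,
                          grid_shape = c(8, 8, 8), seed_voxels = 2,
                          low_hz = 0.012, high_hz = 0.1, rng_seed = 1) {
  if (any(abs(target_cc) >= 1)) stop("target correlations must be in (-1, 1)")
  set.seed(rng_seed)
  mask <- ellipsoid_mask(grid_shape)
  V <- sum(mask)
  if (length(target_cc) != V)
    stop("need one target per in-mask voxel (", V, ")")
  s <- bandpass(rnorm(n_frames), tr_seconds, low_hz, high_hz)
  s <- (s - mean(s)) / sd(s)
  vox <- matrix(NA_real_, V, n_frames)
  for (v in seq_len(V)) {
    e <- rnorm(n_frames)
    e <- (e - mean(e)) / sd(e)
    w <- target_cc[v]
    vox[v, ] <- w * s + sqrt(1 - w^2) * e
  }
  # seed ROI voxels carry the seed series itself (plus negligible jitter so
  # no two voxels are bit-identical)
  vox[seq_len(seed_voxels), ] <-
    matrix(rep(s, each = seed_voxels), seed_voxels) +
    matrix(rnorm(seed_voxels * n_frames, sd = 1e-6), seed_voxels)
  data <- array(0, c(grid_shape, n_frames))
  flat <- matrix(data, ncol = n_frames)
  flat[as.vector(mask), ] <- vox
  data <- array(flat, c(grid_shape, n_frames))
  roi_mask <- array(FALSE, grid_shape)
  roi_mask[which(mask)[seq_len(seed_voxels)]] <- TRUE
  list(bold = bold4d(data, tr_seconds, brain_mask = mask),
       roi = seed_roi(roi_mask, label = "synthetic-seed"),
       seed_series = s)
}

#' Simulate well-separated Gaussian blobs
#'
#' Utility for clustering validation: `k` isotropic Gaussian clusters at
#' the given centers.
#'
#' @param n_per Points per cluster.
#' @param centers k x d matrix of cluster centers.
#' @param sd Within-cluster standard deviation.
#' @param rng_seed Integer seed.
#' @return List with `points` (n x d) and `labels` (true cluster per row).
#' @export
simulate_blobs <- function(n_per, centers, sd = 0.5, rng_seed = 1) {
  set.seed(rng_seed)
  centers <- as.matrix(centers)
  k <- nrow(centers)
  d <- ncol(centers)
  pts <- do.call(rbind, lapply(seq_len(k), function(j)
    matrix(rnorm(n_per * d, sd = sd), n_per, d) +
      matrix(centers[j, ], n_per, d, byrow = TRUE)))
  list(points = pts, labels = rep(seq_len(k), each = n_per))
}

#' Write a simulated cohort as a pipeline-readable fixture
#'
#' Writes one 3D NIfTI Fisher-z map per subject, the mask volume, the
#' subjects CSV, a ground-truth JSON and a sidecar JSON (subject order and
#' mask hash).
#'
#' @param cohort A [simulate_cohort()] result.
#' @param out_dir Writable directory (created if needed).
#' @return Invisible list of the paths written (`fc_paths`, `mask`,
#'   `outcomes`, `truth`, `sidecar`).
#' @export
write_fixture <- function(cohort, out_dir) {
  stopifnot(inherits(cohort, "sim_cohort"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  mask_path <- file.path(out_dir, "mask.nii.gz")
  vol <- array(0L, dim(cohort$mask))
  vol[cohort$mask] <- 1L
  RNifti::writeNifti(RNifti::asNifti(vol), mask_path)
  fc_paths <- vapply(seq_len(nrow(cohort$fc)), function(i) {
    p <- file.path(out_dir, paste0(cohort$records$subject_id[i], ".nii.gz"))
    write_nifti_masked(cohort$fc[i, ], cohort$mask, p)
    p
  }, character(1))
  out_path <- file.path(out_dir, "outcomes.csv")
  write_outcomes(cohort$records, out_path)
  truth_path <- file.path(out_dir, "truth.json")
  jsonlite::write_json(cohort$truth, truth_path, auto_unbox = TRUE,
                       digits = NA)
  sidecar_path <- file.path(out_dir, "cohort.json")
  jsonlite::write_json(list(subject_ids = cohort$records$subject_id,
                            mask_hash = mask_hash(cohort$mask),
                            n_voxels = ncol(cohort$fc)),
                       sidecar_path, auto_unbox = TRUE)
  invisible(list(fc_paths = fc_paths, mask = mask_path,
                 outcomes = out_path, truth = truth_path,
                 sidecar = sidecar_path))
}

#' Reload a fixture directory into cohort form
#'
#' @param dir Directory written by [write_fixture()].
#' @return List with `fc` (subjects x voxels matrix), `records`,
#'   `outcome`, `mask_hash`.
#' @export
read_fixture <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "cohort.json"),
                              simplifyVector = TRUE)
  oc <- read_outcomes(file.path(dir, "outcomes.csv"))
  paths <- file.path(dir, paste0(meta$subject_ids, ".nii.gz"))
  fc <- read_fc_cohort(paths, file.path(dir, "mask.nii.gz"),
                       subject_ids = meta$subject_ids)
  if (!identical(attr(fc, "mask_hash")[[1]], meta$mask_hash))
    stop("mask hash mismatch: fixture may be misaligned")
  list(fc = fc, records = oc$records, outcome = oc$outcome,
       mask_hash = meta$mask_hash)
}
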