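#' 4D BOLD container
#'
#' Light wrapper around an x-y-z-T array with its repetition time, optional
#' voxel-to-world affine and brain mask.
#'
#' @param data 4-dimensional numeric array (x, y, z, T).
#' @param tr_seconds Repetition time in seconds.
#' @param affine Optional 4 x 4 voxel-to-world transform.
#' @param brain_mask Optional logical x-y-z array; defaults to all `TRUE`.
#' @return Object of class `bold4d`.
#' @export
bold4d <- function(data, tr_seconds, affine = NULL, brain_mask = NULL) {
  if (length(dim(data)) != 4) stop("data must be a 4D array")
  if (dim(data)[4] < 2) stop("need at least 2 frames")
  if (is.null(brain_mask)) brain_mask <- array(TRUE, dim(data)[1:3])
  if (!identical(dim(brain_mask), dim(data)[1:3]))
    stop("brain mask shape must match spatial dimensions")
  if (!any(brain_mask)) stop("empty brain mask")
  if (is.null(affine)) affine <- diag(4)
  structure(list(data = data, tr_seconds = tr_seconds, affine = affine,
                 brain_mask = brain_mask), class = "bold4d")
}

#' Seed region of interest
#'
#' @param mask Logical x-y-z array marking the seed voxels.
#' @param label Text label.
#' @param mni_center Optional length-3 MNI coordinate (mm), metadata only.
#' @return Object of class `seed_roi`.
#' @export
seed_roi <- function(mask, label = "seed", mni_center = NULL) {
  if (!any(mask)) stop("empty seed ROI")
  structure(list(mask = mask, label = label, mni_center = mni_center),
            class = "seed_roi")
}

#' Mean seed time series
#'
#' Unweighted mean over the ROI voxels at each frame.
#'
#' @param bold A [bold4d()].
#' @param roi A [seed_roi()]; must lie inside the brain mask.
#' @return Numeric vector of length T.
#' @export
seed_timeseries <- function(bold, roi) {
  stopifnot(inherits(bold, "bold4d"), inherits(roi, "seed_roi"))
  if (!identical(dim(roi$mask), dim(bold$brain_mask)))
    stop("ROI grid does not match BOLD grid")
  if (any(roi$mask & !bold$brain_mask))
    stop("ROI extends outside the brain mask")
  T_ <- dim(bold$data)[4]
  m <- matrix(bold$data, ncol = T_)
  colMeans(m[as.vector(roi$mask), , drop = FALSE])
}

#' Fisher z transform of correlations
#'
#' `z = atanh(cc)` after clipping `cc` into `[-clip, clip]` so z stays
#' finite.
#'
#' @param cc Correlation values.
#' @param clip Clipping bound in (0, 1); default `1 - 1e-7`.
#' @return Fisher-z values.
#' @export
fisher_z <- function(cc, clip = 1 - 1e-7) {
  if (!(clip > 0 && clip < 1)) stop("clip must be in (0, 1)")
  atanh(pmin(pmax(cc, -clip), clip))
}

#' Seed-based functional connectivity map
#'
#' Pearson correlation of every in-mask voxel's series with the mean seed
#' series over the uncensored frames, Fisher-z transformed. Voxels with
#' zero variance get `z = 0` with a warning (they carry no signal and would
#' otherwise produce NaN).
#'
#' @inheritParams seed_timeseries
#' @param clip Correlation clipping bound before `atanh`.
#' @param censored Optional logical vector of length T; censored frames are
#'   excluded from the correlation.
#' @param subject_id Identifier stored with the map.
#' @return Object of class `fc_map`: `z` (numeric, one value per in-mask
#'   voxel in column-major mask order), `brain_mask`, `affine`,
#'   `subject_id`.
#' @export
seed_fc <- function(bold, roi, clip = 1 - 1e-7, censored = NULL,
                    subject_id = "subject") {
  s <- seed_timeseries(bold, roi)
  T_ <- length(s)
  keep <- if (is.null(censored)) rep(TRUE, T_) else !censored
  if (sum(keep) < 10) stop("fewer than 10 uncensored frames")
  s <- s[keep]
  if (sd(s) == 0) stop("zero-variance seed series")
  m <- matrix(bold$data, ncol = T_)[as.vector(bold$brain_mask), keep,
                                    drop = FALSE]
  v <- apply(m, 1, sd)
  cc <- rep(0, nrow(m))
  ok <- v > 0
  if (any(!ok))
    warning(sum(!ok), " zero-variance voxel(s) set to z = 0")
  if (any(ok)) cc[ok] <- drop(cor(t(m[ok, , drop = FALSE]), s))
  structure(list(z = fisher_z(cc, clip), brain_mask = bold$brain_mask,
                 affine = bold$affine, subject_id = subject_id),
            class = "fc_map")
}

#' @export
print.fc_map <- function(x, ...) {
  cat("<fc_map>", x$subject_id, "|", sum(x$brain_mask), "in-mask voxels",
      sprintf("| z range [%.3f, %.3f]\n", min(x$z), max(x$z)))
  invisible(x)
}
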