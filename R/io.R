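#' Read a subjects table with outcome and covariates
#'
#' Expects a CSV with header `subject_id,duration,event` plus any covariate
#' columns (the prediction pipeline uses `age,sex,edu,cpd,hm`). Durations
#' must be positive, events binary, subject IDs unique.
#'
#' @param path CSV file path.
#' @return List with `records` (data frame, subject order preserved) and
#'   `outcome` (a [surv_outcome()]).
#' @export
read_outcomes <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "duration", "event")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$subject_id))
    stop("duplicated subject_id: ",
         paste(unique(df$subject_id[duplicated(df$subject_id)]),
               collapse = ", "))
  bad <- which(!is.finite(df$duration) | df$duration <= 0)
  if (length(bad) > 0)
    stop("non-positive or missing duration at row(s): ",
         paste(bad, collapse = ", "))
  bad <- which(!(df$event %in% c(0, 1)))
  if (length(bad) > 0)
    stop("non-binary event at row(s): ", paste(bad, collapse = ", "))
  covars <- setdiff(names(df), need)
  for (cv in covars) {
    if (!is.numeric(df[[cv]]) || anyNA(df[[cv]]))
      stop("covariate '", cv, "' must be numeric without missing values")
  }
  list(records = df, outcome = surv_outcome(df$duration, df$event))
}

#' Write a subjects table
#'
#' @param records Data frame with at least `subject_id,duration,event`.
#' @param path Output CSV path.
#' @export
write_outcomes <- function(records, path) {
  write.csv(records, path, row.names = FALSE, quote = FALSE)
}

affines_match <- function(a, b, tol = 1e-4) {
  max(abs(a - b)) <= tol
}

#' Read a NIfTI volume restricted to a mask
#'
#' Loads a 3D (or 4D) NIfTI image and a mask volume on the same grid and
#' returns the in-mask values. Grid dimensions must match exactly and the
#' affines must agree to `tol` elementwise.
#'
#' @param path Image path (NIfTI-1).
#' @param mask_path Mask volume path; nonzero voxels define the mask.
#' @param tol Affine agreement tolerance.
#' @return List with `values` (vector for 3D input, frames x voxels matrix
#'   for 4D), `mask` (logical array), `dim`, `affine`.
#' @export
read_nifti_masked <- function(path, mask_path, tol = 1e-4) {
  img <- RNifti::readNifti(path)
  msk <- RNifti::readNifti(mask_path)
  dimg <- dim(img)
  dmsk <- dim(msk)
  if (!identical(dimg[1:3], dmsk[1:3]))
    stop("grid mismatch: image ", paste(dimg, collapse = "x"),
         " vs mask ", paste(dmsk, collapse = "x"))
  a1 <- unclass(RNifti::xform(img))
  a2 <- unclass(RNifti::xform(msk))
  if (!affines_match(a1, a2, tol))
    stop("affine mismatch beyond tolerance ", tol)
  mask <- array(as.array(msk) != 0, dmsk[1:3])
  if (!any(mask)) stop("mask contains 0 voxels")
  vals <- if (length(dimg) == 4) {
    t(matrix(as.array(img), ncol = dimg[4])[as.vector(mask), , drop = FALSE])
  } else {
    as.array(img)[mask]
  }
  list(values = vals, mask = mask, dim = dimg, affine = a1)
}

#' Write in-mask values as a 3D NIfTI volume
#'
#' Out-of-mask voxels are written as zero; data are stored as float32.
#'
#' @param values Numeric vector, one value per in-mask voxel (column-major
#'   mask order).
#' @param mask Logical 3D array.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param template Optional NIfTI image or path supplying the affine.
#' @return The path, invisibly.
#' @export
write_nifti_masked <- function(values, mask, path, template = NULL) {
  if (length(values) != sum(mask))
    stop("value count (", length(values), ") does not match mask size (",
         sum(mask), ")")
  vol <- array(0, dim(mask))
  vol[mask] <- values
  img <- if (is.null(template)) RNifti::asNifti(vol, datatype = "float")
  else RNifti::asNifti(vol, reference = template, datatype = "float")
  RNifti::writeNifti(img, path)
  invisible(path)
}

mask_hash <- function(mask) {
  f <- tempfile()
  on.exit(unlink(f))
  writeBin(as.integer(mask), f)
  unname(tools::md5sum(f))
}

#' Assemble a cohort FC matrix from per-subject NIfTI maps
#'
#' Reads one 3D Fisher-z map per subject, all on the mask's grid, into a
#' subjects x voxels matrix (column-major in-mask order).
#'
#' @param paths Character vector of per-subject NIfTI paths.
#' @param mask_path Mask volume path.
#' @param subject_ids Optional row names; defaults to file base names.
#' @return Subjects x voxels numeric matrix with attributes `mask`
#'   (logical array) and `mask_hash`.
#' @export
read_fc_cohort <- function(paths, mask_path, subject_ids = NULL) {
  first <- read_nifti_masked(paths[1], mask_path)
  mat <- matrix(NA_real_, length(paths), sum(first$mask))
  mat[1, ] <- first$values
  for (i in seq_along(paths)[-1]) {
    mat[i, ] <- read_nifti_masked(paths[i], mask_path)$values
  }
  rownames(mat) <- if (is.null(subject_ids))
    sub("\\.nii(\\.gz)?$", "", basename(paths)) else subject_ids
  attr(mat, "mask") <- first$mask
  attr(mat, "mask_hash") <- mask_hash(first$mask)
  mat
}

#' Cache a cohort FC matrix as a binary container with JSON sidecar
#'
#' The matrix is stored as little-endian doubles; the sidecar records the
#' dimensions, subject order and mask hash so silent misalignment is
#' detectable on reload.
#'
#' @param fc Subjects x voxels matrix (as from [read_fc_cohort()]).
#' @param path Output binary path; the sidecar is written at `path + ".json"`.
#' @export
write_fc_cache <- function(fc, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.vector(fc), con, size = 8, endian = "little")
  sidecar <- list(n_subjects = nrow(fc), n_voxels = ncol(fc),
                  subject_ids = rownames(fc),
                  mask_hash = attr(fc, "mask_hash"))
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Reload a cached cohort FC matrix
#'
#' @param path Binary path written by [write_fc_cache()].
#' @return Subjects x voxels matrix with `mask_hash` attribute.
#' @export
read_fc_cache <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  n <- meta$n_subjects * meta$n_voxels
  con <- file(path, "rb")
  on.exit(close(con))
  vals <- readBin(con, "double", n = n, size = 8, endian = "little")
  mat <- matrix(vals, meta$n_subjects, meta$n_voxels)
  rownames(mat) <- meta$subject_ids
  attr(mat, "mask_hash") <- meta$mask_hash
  mat
}
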