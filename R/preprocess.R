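#' Framewise displacement from rigid-body motion parameters
#'
#' Scalar head-motion magnitude between consecutive volumes. The default
#' `"enorm"` convention is the Euclidean norm of the six frame-to-frame
#' first differences, with rotations in degrees treated as mm-equivalent.
#' The `"power"` convention converts rotations to arc length on a
#' `rot_radius_mm` sphere (degrees to radians times radius) and takes the
#' L1 norm.
#'
#' @param params T x 6 numeric matrix: three translations (mm) then three
#'   rotations (degrees).
#' @param convention `"enorm"` (default) or `"power"`.
#' @param rot_radius_mm Head radius for the `"power"` convention.
#' @return Numeric vector of length `T - 1`, one displacement per
#'   frame-to-frame transition; all values >= 0.
#' @examples
#' p <- matrix(0, 5, 6); p[3, 1] <- 0.3
#' framewise_displacement(p)  # 0, 0.3, 0.3, 0
#' @export
framewise_displacement <- function(params, convention = c("enorm", "power"),
                                   rot_radius_mm = 50) {
  convention <- match.arg(convention)
  params <- as.matrix(params)
  if (ncol(params) != 6) stop("motion parameters must have 6 columns")
  if (nrow(params) < 2) stop("need at least 2 frames")
  if (anyNA(params) || any(!is.finite(params)))
    stop("non-finite motion parameters")
  d <- diff(params)
  if (convention == "enorm") {
    sqrt(rowSums(d^2))
  } else {
    d[, 4:6] <- d[, 4:6] * pi / 180 * rot_radius_mm
    rowSums(abs(d))
  }
}

#' Censor high-motion volumes
#'
#' Volume `t` (for `t >= 2`) is censored when the displacement of its
#' preceding transition exceeds `threshold_mm`; the first volume is never
#' censored on motion grounds.
#'
#' @param fd Framewise-displacement series of length `T - 1`.
#' @param threshold_mm Positive censoring threshold (default 0.35 mm).
#' @return Logical vector of length `T`; `TRUE` = censored.
#' @export
censor_volumes <- function(fd, threshold_mm = 0.35) {
  if (threshold_mm <= 0) stop("threshold must be > 0")
  c(FALSE, fd > threshold_mm)
}

#' Subject-level motion quality control
#'
#' A subject passes when mean framewise displacement is at most
#' `mean_threshold_mm` and the fraction of censored volumes is at most
#' `max_censor_fraction`.
#'
#' @param fd Framewise-displacement series.
#' @param censored Logical censoring flags per volume (length `T`).
#' @param mean_threshold_mm Mean-FD exclusion threshold (default 0.2 mm).
#' @param max_censor_fraction Maximum tolerated censored fraction
#'   (default 0.2).
#' @return Object of class `qc_report`: `mean_fd`, `censor_fraction`,
#'   `pass`, `reasons` (character; `"mean-fd"` and/or `"censor-fraction"`).
#' @export
qc_subject <- function(fd, censored, mean_threshold_mm = 0.2,
                       max_censor_fraction = 0.2) {
  if (length(fd) == 0) stop("empty fd series")
  mean_fd <- mean(fd)
  frac <- mean(censored)
  reasons <- character()
  if (mean_fd > mean_threshold_mm) reasons <- c(reasons, "mean-fd")
  if (frac > max_censor_fraction) reasons <- c(reasons, "censor-fraction")
  structure(list(mean_fd = mean_fd, censor_fraction = frac,
                 pass = length(reasons) == 0L, reasons = reasons),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("<qc_report>", if (x$pass) "PASS" else
    paste("FAIL:", paste(x$reasons, collapse = ", ")),
    sprintf("| mean FD %.4f mm | censored %.1f%%\n",
            x$mean_fd, 100 * x$censor_fraction))
  invisible(x)
}

as_ts_matrix <- function(series) {
  if (is.matrix(series)) series else matrix(series, ncol = 1)
}

#' Polynomial detrending of time series
#'
#' Removes a polynomial trend of the given order (0 = mean only, up to 3 in
#' routine use) by least-squares projection; residuals are orthogonal to
#' the polynomial basis.
#'
#' @param series Numeric vector (length T) or T x V matrix, time in rows.
#' @param order Polynomial order, >= 0.
#' @return Residual series, same shape as the input.
#' @export
detrend_poly <- function(series, order = 3L) {
  x <- as_ts_matrix(series)
  T_ <- nrow(x)
  if (order < 0) stop("order must be >= 0")
  if (T_ <= order + 1) stop("need more than order + 1 frames")
  basis <- cbind(1, if (order >= 1) stats::poly(seq_len(T_), order))
  res <- qr.resid(qr(basis), x)
  if (is.matrix(series)) res else drop(res)
}

#' Nuisance regression
#'
#' Projects out the column space of the nuisance signals (e.g. white-matter
#' and CSF mean series); residuals are orthogonal to every nuisance column.
#'
#' @param series Numeric vector or T x V matrix, time in rows.
#' @param nuisance T x k full-rank matrix of nuisance regressors.
#' @return Residual series, same shape as the input.
#' @export
regress_nuisance <- function(series, nuisance) {
  x <- as_ts_matrix(series)
  N <- as.matrix(nuisance)
  if (nrow(N) != nrow(x)) stop("nuisance rows must match series length")
  if (ncol(N) >= nrow(N)) stop("more nuisance regressors than frames")
  qn <- qr(N)
  if (qn$rank < ncol(N)) stop("rank-deficient nuisance matrix")
  res <- qr.resid(qn, x)
  if (is.matrix(series)) res else drop(res)
}

#' Band-pass filtering of BOLD time series
#'
#' Retains low-frequency fluctuations in `[low_hz, high_hz]`. The default
#' realization is an ideal frequency-domain filter: Fourier bins whose
#' frequency falls inside the band (inclusive) are kept, all others --
#' including DC -- are zeroed. A zero-phase Butterworth alternative
#' (order 4, via the `signal` package) is available with
#' `method = "butterworth"`.
#'
#' @param series Numeric vector or T x V matrix, time in rows.
#' @param tr_seconds Repetition time (sampling interval), seconds.
#' @param low_hz,high_hz Passband edges; must satisfy
#'   `0 < low < high < 1 / (2 tr)`.
#' @param method `"ideal"` (default) or `"butterworth"`.
#' @return Filtered series, same shape as the input.
#' @export
bandpass <- function(series, tr_seconds, low_hz = 0.012, high_hz = 0.1,
                     method = c("ideal", "butterworth")) {
  method <- match.arg(method)
  nyq <- 1 / (2 * tr_seconds)
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < nyq))
    stop("band must satisfy 0 < low < high < Nyquist (", format(nyq), " Hz)")
  x <- as_ts_matrix(series)
  T_ <- nrow(x)
  if (method == "ideal") {
    k <- seq_len(T_) - 1
    freq <- pmin(k, T_ - k) / (T_ * tr_seconds)
    keep <- freq >= low_hz & freq <= high_hz
    xf <- mvfft(x)
    xf[!keep, ] <- 0
    res <- Re(mvfft(xf, inverse = TRUE)) / T_
  } else {
    if (!requireNamespace("signal", quietly = TRUE))
      stop("method 'butterworth' requires the signal package")
    bf <- signal::butter(4, c(low_hz, high_hz) / nyq, type = "pass")
    res <- apply(x, 2, function(col)
      signal::filtfilt(bf, col - mean(col)))
  }
  if (is.matrix(series)) res else drop(res)
}

#' Full time-series cleaning chain
#'
#' Convenience wrapper applying, in order: polynomial detrending, nuisance
#' regression (optional) and band-pass filtering, then dropping censored
#' frames listwise (optional). This mirrors the cleaning applied before
#' seed-connectivity computation.
#'
#' @inheritParams bandpass
#' @inheritParams detrend_poly
#' @param nuisance Optional T x k nuisance matrix.
#' @param censored Optional logical vector of length T; censored frames are
#'   removed after filtering.
#' @return Cleaned series (frames reduced if `censored` was given).
#' @export
clean_timeseries <- function(series, tr_seconds, order = 3L, nuisance = NULL,
                             low_hz = 0.012, high_hz = 0.1, censored = NULL,
                             method = c("ideal", "butterworth")) {
  x <- detrend_poly(series, order)
  if (!is.null(nuisance)) x <- regress_nuisance(x, nuisance)
  x <- bandpass(x, tr_seconds, low_hz, high_hz, match.arg(method))
  if (!is.null(censored)) {
    x <- as_ts_matrix(x)[!censored, , drop = FALSE]
    if (!is.matrix(series)) x <- drop(x)
  }
  x
}

#' Read motion parameters from a whitespace-delimited file
#'
#' Accepts AFNI-style (`roll pitch yaw dS dL dP`: rotations first) or
#' SPM-style (translations first) T x 6 files and returns the internal
#' convention (translations mm, then rotations degrees).
#'
#' @param path File with T rows and 6 whitespace-separated columns.
#' @param dialect `"spm"` (translations first, default) or `"afni"`
#'   (rotations first).
#' @return T x 6 numeric matrix, translations then rotations.
#' @export
read_motion_params <- function(path, dialect = c("spm", "afni")) {
  dialect <- match.arg(dialect)
  m <- as.matrix(read.table(path))
  if (ncol(m) != 6) stop("expected 6 columns in ", path)
  colnames(m) <- NULL
  if (dialect == "afni") m <- m[, c(4:6, 1:3)]
  m
}
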