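#' Mass-univariate voxel-wise Cox screening
#'
#' Fits, at every voxel, a Cox proportional-hazards model with that voxel's
#' Fisher-z connectivity as the sole covariate, giving per-voxel beta maps
#' (log hazard ratios), standard errors, two-sided Wald p-values and hazard
#' ratios `exp(beta)`. Voxels with a degenerate (constant) column or a
#' monotone likelihood are flagged and must be excluded downstream.
#'
#' @param fc_cohort Subjects x voxels matrix of Fisher-z values.
#' @param outcome A [surv_outcome()] with at least 2 events.
#' @inheritParams fit_cox
#' @return Object of class `stat_maps`: data frame columns `beta`, `se`,
#'   `z_wald`, `p_value`, `hr`, `status` (0 converged, 1 separated,
#'   2 not converged, 3 degenerate), plus attributes `n`, `n_events`.
#' @export
voxelwise_cox <- function(fc_cohort, outcome, ties = c("breslow", "efron"),
                          tol = 1e-8, max_iter = 100L, beta_cap = 50) {
  outcome <- as_surv_outcome(outcome)
  ties <- match.arg(ties)
  Z <- as.matrix(fc_cohort)
  storage.mode(Z) <- "double"
  if (nrow(Z) != outcome$n)
    stop("FC rows (", nrow(Z), ") do not match outcome length (",
         outcome$n, ")")
  if (anyNA(Z) || any(!is.finite(Z))) stop("non-finite FC values")
  if (outcome$n_events < 2) stop("need at least 2 observed events")
  res <- cpp_cox_screen(Z, outcome$durations, outcome$events,
                        if (ties == "breslow") 0L else 1L,
                        tol, as.integer(max_iter), beta_cap)
  z <- res$beta / res$se
  p <- 2 * pnorm(-abs(z))
  out <- data.frame(beta = res$beta, se = res$se, z_wald = z, p_value = p,
                    hr = exp(res$beta), status = res$status)
  attr(out, "n") <- outcome$n
  attr(out, "n_events") <- outcome$n_events
  attr(out, "ties") <- ties
  class(out) <- c("stat_maps", "data.frame")
  out
}

#' Threshold beta maps into protective and risk circuit masks
#'
#' A converged voxel enters the protective mask when `beta < 0` and
#' `p < alpha` (hazard ratio below 1: stronger connectivity, longer time to
#' relapse) and the risk mask when `beta > 0` and `p < alpha`. Flagged
#' voxels (separated, non-converged or degenerate) are never included, so
#' the two masks are disjoint by construction.
#'
#' @param stats A [voxelwise_cox()] result.
#' @param alpha Two-sided significance threshold (default 0.001).
#' @return Object of class `circuit_masks`: logical vectors `protective`
#'   and `risk` plus the `alpha` used.
#' @export
threshold_maps <- function(stats, alpha = 0.001) {
  stopifnot(inherits(stats, "stat_maps"))
  if (!(alpha > 0 && alpha < 1)) stop("alpha must be in (0, 1)")
  ok <- stats$status == 0L & is.finite(stats$p_value)
  sig <- ok & stats$p_value < alpha
  structure(list(protective = sig & stats$beta < 0,
                 risk = sig & stats$beta > 0, alpha = alpha),
            class = "circuit_masks")
}

#' @export
print.circuit_masks <- function(x, ...) {
  cat("<circuit_masks> alpha =", x$alpha, "| protective:",
      sum(x$protective), "| risk:", sum(x$risk), "voxels\n")
  invisible(x)
}

#' Composite protective and risk indices
#'
#' `indexP` is the linear sum of Fisher-z connectivity over the protective
#' mask, `indexR` over the risk mask. An empty mask yields 0 with a
#' warning.
#'
#' @param fc One subject's Fisher-z vector, an `fc_map`, or a subjects x
#'   voxels matrix.
#' @param masks A [threshold_maps()] result on the same voxel grid.
#' @return Data frame with columns `indexP` and `indexR`, one row per
#'   subject.
#' @export
composite_indices <- function(fc, masks) {
  stopifnot(inherits(masks, "circuit_masks"))
  if (inherits(fc, "fc_map")) fc <- fc$z
  m <- if (is.matrix(fc)) fc else matrix(fc, nrow = 1)
  if (ncol(m) != length(masks$protective))
    stop("voxel grid mismatch: FC has ", ncol(m), " voxels, masks have ",
         length(masks$protective))
  if (!any(masks$protective))
    warning("empty protective mask; indexP = 0")
  if (!any(masks$risk))
    warning("empty risk mask; indexR = 0")
  data.frame(
    indexP = as.vector(m[, masks$protective, drop = FALSE] %*%
                         rep(1, sum(masks$protective))),
    indexR = as.vector(m[, masks$risk, drop = FALSE] %*%
                         rep(1, sum(masks$risk))))
}
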