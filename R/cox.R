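#' Fit a Cox proportional-hazards model by partial likelihood
#'
#' Maximizes the log partial likelihood `h(X, t) = h0(t) exp(sum_j x_j b_j)`
#' by Newton-Raphson from `beta = 0` with step-halving whenever a step would
#' decrease the likelihood. Standard errors come from the inverse observed
#' information at the maximum; Wald z and two-sided p-values are attached.
#' A coefficient whose magnitude exceeds `beta_cap` signals a monotone
#' (separable) likelihood: the fit is returned flagged non-converged rather
#' than failing, so mass-univariate callers can skip such covariates.
#'
#' @param outcome A [surv_outcome()] (at least one event required).
#' @param covariates Numeric matrix or data frame, subjects x p; no missing
#'   values, no constant column.
#' @param ties Tie handling for the partial likelihood: `"breslow"`
#'   (default) or `"efron"`.
#' @param tol Convergence tolerance on the score (gradient) norm.
#' @param max_iter Maximum Newton-Raphson iterations.
#' @param beta_cap Magnitude beyond which a coefficient is declared
#'   separated (monotone likelihood).
#' @return Object of class `cox_fit`: `coefficients` (log hazard ratios),
#'   `se`, `z_wald`, `p_values`, `hazard_ratio`, `loglik`, `loglik_null`,
#'   `converged`, `capped`, `n`, `n_events`, `ties`, `iterations`,
#'   `var_names`, and `score0`/`info0` (score vector and information at
#'   `beta = 0`, used by score tests).
#' @examples
#' out <- surv_outcome(c(1, 2, 3, 4), c(1, 1, 1, 1))
#' fit <- fit_cox(out, matrix(c(1, 0, 1, 0), ncol = 1))
#' fit$coefficients  # log((1 + sqrt(17)) / 2)
#' @export
fit_cox <- function(outcome, covariates, ties = c("breslow", "efron"),
                    tol = 1e-8, max_iter = 100L, beta_cap = 50) {
  outcome <- as_surv_outcome(outcome)
  ties <- match.arg(ties)
  X <- as.matrix(covariates)
  storage.mode(X) <- "double"
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (nrow(X) != outcome$n)
    stop("covariate rows (", nrow(X), ") do not match outcome length (",
         outcome$n, ")")
  if (anyNA(X) || any(!is.finite(X))) stop("non-finite covariate values")
  if (outcome$n_events < 1L)
    stop("no-events: at least one observed event is required")
  sds <- apply(X, 2, sd)
  if (any(sds < 1e-12))
    stop("degenerate-covariate: zero variance in column(s) ",
         paste(colnames(X)[sds < 1e-12], collapse = ", "))
  qx <- qr(scale(X, center = TRUE, scale = FALSE))
  if (qx$rank < ncol(X))
    stop("degenerate-covariate: collinear column(s) ",
         paste(colnames(X)[qx$pivot[seq(qx$rank + 1L, ncol(X))]],
               collapse = ", "))
  mu <- colMeans(X)
  res <- cpp_cox_fit(sweep(X, 2, mu), outcome$durations, outcome$events,
                     if (ties == "breslow") 0L else 1L,
                     tol, as.integer(max_iter), beta_cap)
  beta <- as.numeric(res$beta)
  se <- as.numeric(res$se)
  names(beta) <- names(se) <- colnames(X)
  z <- beta / se
  p <- 2 * pnorm(-abs(z))
  if (res$capped)
    warning("monotone partial likelihood detected (|beta| > ", beta_cap,
            "); fit flagged non-converged")
  else if (!res$converged)
    warning("Newton-Raphson did not converge in ", max_iter, " iterations")
  structure(list(coefficients = beta, se = se, z_wald = z, p_values = p,
                 hazard_ratio = exp(beta), loglik = res$loglik,
                 loglik_null = res$loglik_null,
                 converged = isTRUE(res$converged),
                 capped = isTRUE(res$capped), n = outcome$n,
                 n_events = outcome$n_events, ties = ties,
                 iterations = res$iter, var_names = colnames(X),
                 means = mu, score0 = as.numeric(res$score0),
                 info0 = res$info0),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat("<cox_fit> n =", x$n, "| events =", x$n_events, "| ties =", x$ties,
      if (!x$converged) "| NOT CONVERGED" else "", "\n")
  print(data.frame(beta = x$coefficients, HR = x$hazard_ratio, se = x$se,
                   z = x$z_wald, p = x$p_values, row.names = x$var_names))
  cat("log partial likelihood:", format(x$loglik), "(null:",
      format(x$loglik_null), ")\n")
  invisible(x)
}

#' Two-sided Wald p-values from a Cox fit
#'
#' `p = 2 * Phi(-|beta / se|)` per coefficient, using the standard normal
#' tail. Requires a converged fit with positive standard errors.
#'
#' @param fit A [fit_cox()] result.
#' @return Named numeric vector of p-values in (0, 1].
#' @export
wald_pvalue <- function(fit) {
  stopifnot(inherits(fit, "cox_fit"))
  if (!fit$converged) stop("fit did not converge; Wald p-values undefined")
  if (anyNA(fit$se) || any(fit$se <= 0))
    stop("non-positive standard error")
  2 * pnorm(-abs(fit$coefficients / fit$se))
}

#' Linear predictor (risk score) from a Cox fit
#'
#' `score_i = sum_j x_ij beta_j` on the raw covariate scale. Column names
#' must match the fit in the same order.
#'
#' @param fit A [fit_cox()] result.
#' @param covariates Matrix or data frame with the fit's columns.
#' @return Numeric risk score per row.
#' @export
linear_predictor <- function(fit, covariates) {
  stopifnot(inherits(fit, "cox_fit"))
  X <- as.matrix(covariates)
  if (ncol(X) != length(fit$coefficients))
    stop("covariate count mismatch: fit has ", length(fit$coefficients),
         ", supplied ", ncol(X))
  if (!is.null(colnames(X)) && !identical(colnames(X), fit$var_names))
    stop("covariate names/order mismatch: expected ",
         paste(fit$var_names, collapse = ", "))
  as.vector(X %*% fit$coefficients)
}

#' Score (log-rank type) test at beta = 0
#'
#' Chi-squared statistic `U' I^-1 U` from the partial-likelihood score and
#' information evaluated at `beta = 0`. For a single binary covariate with
#' Breslow ties this equals the classical log-rank statistic.
#'
#' @param outcome A [surv_outcome()].
#' @param covariates Single-or-multi column covariate matrix.
#' @inheritParams fit_cox
#' @return List with `statistic`, `df`, `p_value`.
#' @export
cox_score_test <- function(outcome, covariates, ties = c("breslow", "efron")) {
  ties <- match.arg(ties)
  fit <- suppressWarnings(fit_cox(outcome, covariates, ties = ties,
                                  max_iter = 0L))
  U <- fit$score0
  I <- as.matrix(fit$info0)
  stat <- drop(t(U) %*% solve(I, U))
  df <- length(U)
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE))
}
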