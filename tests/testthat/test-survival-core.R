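test_that("partial-likelihood maximum matches the closed-form worked case", {
  out <- surv_outcome(c(1, 2, 3, 4), c(1, 1, 1, 1))
  fit <- fit_cox(out, matrix(c(1, 0, 1, 0), ncol = 1))
  # stationary point: u^2 - u - 4 = 0, beta = log((1 + sqrt(17)) / 2)
  expect_equal(unname(fit$coefficients), log((1 + sqrt(17)) / 2),
               tolerance = 1e-6)
  expect_true(fit$converged)
  expect_gte(fit$loglik, fit$loglik_null)
  expect_equal(unname(fit$hazard_ratio), exp(unname(fit$coefficients)))
})

test_that("fit_cox agrees with brute-force grid maximization on random problems", {
  set.seed(101)
  for (rep in 1:25) {
    pr <- rand_problem(sample(4:8, 1))
    fit <- suppressWarnings(fit_cox(pr$outcome, matrix(pr$x, ncol = 1)))
    if (!fit$converged) next  # separable draws are covered elsewhere
    bstar <- bf_beta_grid(pr$outcome$durations, pr$outcome$events, pr$x)
    expect_lt(abs(unname(fit$coefficients) - bstar), 1e-3)
    expect_equal(fit$loglik,
                 bf_breslow_loglik(unname(fit$coefficients),
                                   pr$outcome$durations,
                                   pr$outcome$events, pr$x),
                 tolerance = 1e-10)
  }
})

test_that("monotone likelihood is flagged, not reported as a clean fit", {
  out <- surv_outcome(c(1, 2, 3, 4), c(1, 1, 1, 1))
  # x = (1,1,0,0) perfectly orders the earliest events; score > 0 for all beta
  expect_warning(fit <- fit_cox(out, matrix(c(1, 1, 0, 0), ncol = 1)),
                 "monotone")
  expect_false(fit$converged)
  expect_true(fit$capped)
})

test_that("degenerate and empty inputs error with named conditions", {
  out <- surv_outcome(c(1, 2, 3, 4), c(1, 1, 1, 1))
  expect_error(fit_cox(out, matrix(1, 4, 1)), "degenerate-covariate")
  expect_error(
    fit_cox(surv_outcome(1:4, c(0, 0, 0, 0)), matrix(rnorm(4), ncol = 1)),
    "no-events")
  x <- cbind(a = c(1, 0, 1, 0), b = c(2, 0, 2, 0))
  expect_error(fit_cox(out, x), "degenerate-covariate.*b")
  expect_error(surv_outcome(c(0, 1), c(1, 1)), "> 0")
  expect_error(surv_outcome(c(1, 2), c(1, 2)), "0/1")
})

test_that("both tie conventions reproduce an independent Cox implementation", {
  skip_if_not_installed("survival")
  set.seed(7)
  n <- 40
  x <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("a", "b", "c")))
  tm <- ceiling(rexp(n, exp(0.4 * x[, 1])) * 10)  # integer times force ties
  ev <- rbinom(n, 1, 0.8)
  if (sum(ev) < 2) ev[1:2] <- 1L
  out <- surv_outcome(tm, ev)
  for (t in c("breslow", "efron")) {
    mine <- fit_cox(out, x, ties = t)
    ref <- survival::coxph(survival::Surv(tm, ev) ~ x, ties = t)
    expect_equal(unname(mine$coefficients), unname(coef(ref)),
                 tolerance = 1e-6)
    expect_equal(unname(mine$se), unname(sqrt(diag(vcov(ref)))),
                 tolerance = 1e-6)
    expect_equal(mine$loglik, ref$loglik[2], tolerance = 1e-8)
  }
})

test_that("rescaling a covariate rescales beta and leaves loglik/p alone", {
  set.seed(11)
  pr <- rand_problem(8)
  x1 <- matrix(pr$x, ncol = 1)
  f1 <- fit_cox(pr$outcome, x1)
  f2 <- fit_cox(pr$outcome, x1 * 10)
  expect_equal(unname(f1$coefficients), 10 * unname(f2$coefficients),
               tolerance = 1e-8)
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-8)
  expect_equal(f1$p_values, f2$p_values, tolerance = 1e-8)
})

test_that("score statistic at beta = 0 equals the log-rank statistic", {
  skip_if_not_installed("survival")
  set.seed(21)
  n <- 30
  g <- rbinom(n, 1, 0.5)
  tm <- rexp(n, exp(0.8 * g))
  ev <- rbinom(n, 1, 0.85)
  if (sum(ev[g == 0]) == 0 || sum(ev[g == 1]) == 0) ev[1:2] <- 1L
  st <- cox_score_test(surv_outcome(tm, ev), matrix(g, ncol = 1))
  ref <- survival::survdiff(survival::Surv(tm, ev) ~ g)
  expect_equal(st$statistic, ref$chisq, tolerance = 1e-6)
})

test_that("Wald p-values follow the two-sided normal tail", {
  out <- surv_outcome(c(1, 2, 3, 4, 5, 6), c(1, 1, 1, 1, 1, 1))
  fit <- fit_cox(out, matrix(c(0.3, -1, 2, 0.1, -0.4, 1.2), ncol = 1))
  expect_equal(unname(wald_pvalue(fit)),
               2 * pnorm(-abs(unname(fit$coefficients / fit$se))))
  # reference z values against published normal quantiles
  expect_equal(2 * pnorm(-1.959964), 0.05, tolerance = 1e-6)
  expect_equal(2 * pnorm(-3.290527), 0.001, tolerance = 1e-6)
  fit$se[1] <- 0
  expect_error(wald_pvalue(fit), "standard error")
})

test_that("linear predictor is the raw inner product and shift-invariant in differences", {
  out <- surv_outcome(c(3, 1, 4, 2, 6, 5), c(1, 1, 0, 1, 1, 1))
  set.seed(5)
  x <- matrix(rnorm(12), 6, 2, dimnames = list(NULL, c("a", "b")))
  fit <- fit_cox(out, x)
  expect_equal(linear_predictor(fit, x), as.vector(x %*% fit$coefficients))
  # hand-check: beta = (1, -1) at x = (2, 2) gives 0
  f0 <- fit
  f0$coefficients <- c(a = 1, b = -1)
  expect_equal(linear_predictor(f0, matrix(c(2, 2), 1)), 0)
  # shifting a column re-fits to the same beta; score differences unchanged
  x2 <- x
  x2[, 1] <- x2[, 1] + 100
  fit2 <- fit_cox(out, x2)
  s1 <- linear_predictor(fit, x)
  s2 <- linear_predictor(fit2, x2)
  expect_equal(diff(s1), diff(s2), tolerance = 1e-6)
  expect_error(linear_predictor(fit, x[, c(2, 1)]), "mismatch")
})

test_that("Kaplan-Meier matches hand product-limit calculations", {
  km <- kaplan_meier(surv_outcome(c(5, 10, 15), c(1, 1, 1)))
  expect_equal(km$survival, c(2 / 3, 1 / 3, 0))
  km2 <- kaplan_meier(surv_outcome(c(2, 4, 4, 6), c(1, 0, 1, 0)))
  expect_equal(km_survival_at(km2, c(2, 4)), c(0.75, 0.75 * (1 - 1 / 3)))
  expect_equal(km_survival_at(km2, 0), 1)
  all_cens <- kaplan_meier(surv_outcome(c(3, 6, 9), c(0, 0, 0)))
  expect_true(all(all_cens$survival == 1))
  expect_true(all(diff(km2$survival) <= 0))
})

test_that("Kaplan-Meier without censoring is the empirical survival function", {
  set.seed(9)
  d <- sample(1:50, 20, replace = TRUE)
  km <- kaplan_meier(surv_outcome(d, rep(1, 20)))
  expect_equal(km$survival, vapply(km$time, function(t) mean(d > t),
                                   numeric(1)))
  skip_if_not_installed("survival")
  ref <- survival::survfit(survival::Surv(d, rep(1, 20)) ~ 1)
  expect_equal(km$survival, ref$surv)
})
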