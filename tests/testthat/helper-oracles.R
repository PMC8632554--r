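# Independent oracles, deliberately naive: brute-force evaluation of the
# Breslow log partial likelihood, grid-search maximization, and exhaustive
# concordant-pair AUC counting.

bf_breslow_loglik <- function(beta, durations, events, x) {
  ll <- 0
  for (t in sort(unique(durations[events == 1]))) {
    deaths <- which(durations == t & events == 1)
    risk <- which(durations >= t)
    ll <- ll + sum(x[deaths] * beta) -
      length(deaths) * log(sum(exp(x[risk] * beta)))
  }
  ll
}

bf_beta_grid <- function(durations, events, x, lo = -12, hi = 12,
                         step = 1e-4) {
  coarse <- seq(lo, hi, by = 0.01)
  ll <- vapply(coarse, bf_breslow_loglik, numeric(1),
               durations = durations, events = events, x = x)
  c0 <- coarse[which.max(ll)]
  fine <- seq(c0 - 0.02, c0 + 0.02, by = step)
  llf <- vapply(fine, bf_breslow_loglik, numeric(1),
                durations = durations, events = events, x = x)
  fine[which.max(llf)]
}

# Mann-Whitney pair count: P(score_pos > score_neg) + 0.5 P(tie)
bf_auc <- function(scores, labels) {
  sp <- scores[labels]
  sn <- scores[!labels]
  tot <- 0
  for (a in sp) for (b in sn) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(sp) * length(sn))
}

# random small single-covariate survival problem with a guaranteed event
rand_problem <- function(n) {
  durations <- sample(1:20, n, replace = TRUE)
  events <- rbinom(n, 1, 0.7)
  if (sum(events) == 0) events[sample(n, 1)] <- 1L
  x <- round(rnorm(n), 2)
  if (sd(x) == 0) x[1] <- x[1] + 1
  list(outcome = surv_outcome(durations, events), x = x)
}

# small planted cohort shared by several tests
make_cohort <- function(n = 40, grid = c(12, 12, 12), seed = 3, ...) {
  simulate_cohort(sim_config(n_subjects = n, grid_shape = grid,
                             rng_seed = seed, ...))
}

adjusted_rand <- function(a, b) {
  if (requireNamespace("mclust", quietly = TRUE))
    return(mclust::adjustedRandIndex(a, b))
  tab <- table(a, b)
  ch2 <- function(x) sum(choose(x, 2))
  idx <- ch2(tab)
  e <- ch2(rowSums(tab)) * ch2(colSums(tab)) / choose(sum(tab), 2)
  mx <- (ch2(rowSums(tab)) + ch2(colSums(tab))) / 2
  (idx - e) / (mx - e)
}
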