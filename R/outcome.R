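#' Censored time-to-relapse outcome
#'
#' Bundles follow-up durations (days) with the relapse indicator. A subject
#' is an event (`1`) if relapse was observed at `duration`, censored (`0`)
#' if follow-up ended relapse-free (administratively, e.g. at day 168).
#'
#' @param durations Positive numeric vector, days until relapse or censoring.
#' @param events Binary vector (0/1 or logical), same length; 1 = relapse
#'   observed, 0 = censored.
#' @return An object of class `surv_outcome`: list with `durations`,
#'   `events`, `n`, `n_events`.
#' @examples
#' surv_outcome(c(5, 30, 168), c(1, 1, 0))
#' @export
surv_outcome <- function(durations, events) {
  durations <- as.numeric(durations)
  if (is.logical(events)) events <- as.integer(events)
  events <- as.integer(events)
  if (length(durations) != length(events))
    stop("durations and events must have equal length")
  if (length(durations) == 0L) stop("empty outcome")
  if (anyNA(durations) || anyNA(events))
    stop("missing values in outcome")
  if (any(durations <= 0))
    stop("all durations must be > 0 (offending rows: ",
         paste(which(durations <= 0), collapse = ", "), ")")
  if (!all(events %in% c(0L, 1L)))
    stop("events must be 0/1 (offending rows: ",
         paste(which(!(events %in% c(0L, 1L))), collapse = ", "), ")")
  structure(list(durations = durations, events = events,
                 n = length(durations), n_events = sum(events)),
            class = "surv_outcome")
}

as_surv_outcome <- function(x) {
  if (inherits(x, "surv_outcome")) return(x)
  if (is.data.frame(x) && all(c("duration", "event") %in% names(x)))
    return(surv_outcome(x$duration, x$event))
  stop("cannot interpret object as a surv_outcome")
}

#' @export
print.surv_outcome <- function(x, ...) {
  cat("<surv_outcome> n =", x$n, "| events =", x$n_events,
      "| censored =", x$n - x$n_events, "\n")
  invisible(x)
}

#' Kaplan-Meier product-limit estimator
#'
#' Nonparametric survival curve for a censored outcome: at each distinct
#' event time the curve drops by the factor `1 - d/r` (deaths over subjects
#' at risk); censored subjects leave the risk set without a drop.
#'
#' @param outcome A [surv_outcome()].
#' @return Object of class `km_estimate`: data frame columns `time` (sorted
#'   distinct observed times), `n_risk`, `n_event`, `n_censor`, `survival`.
#' @examples
#' km <- kaplan_meier(surv_outcome(c(2, 4, 4, 6), c(1, 0, 1, 0)))
#' km$survival  # 0.75 at t = 2, 0.50 at t = 4
#' @export
kaplan_meier <- function(outcome) {
  outcome <- as_surv_outcome(outcome)
  tt <- sort(unique(outcome$durations))
  n_risk <- n_event <- n_censor <- integer(length(tt))
  surv <- numeric(length(tt))
  s <- 1
  for (i in seq_along(tt)) {
    n_risk[i] <- sum(outcome$durations >= tt[i])
    at <- outcome$durations == tt[i]
    n_event[i] <- sum(at & outcome$events == 1L)
    n_censor[i] <- sum(at & outcome$events == 0L)
    if (n_event[i] > 0) s <- s * (1 - n_event[i] / n_risk[i])
    surv[i] <- s
  }
  structure(data.frame(time = tt, n_risk = n_risk, n_event = n_event,
                       n_censor = n_censor, survival = surv),
            class = c("km_estimate", "data.frame"))
}

#' Survival probability at given times from a Kaplan-Meier estimate
#'
#' @param km A [kaplan_meier()] result.
#' @param times Numeric vector of times; `S(t)` is right-continuous and
#'   `S(0) = 1`.
#' @return Numeric vector of survival probabilities.
#' @export
km_survival_at <- function(km, times) {
  stopifnot(inherits(km, "km_estimate"))
  vapply(times, function(t) {
    i <- which(km$time <= t)
    if (length(i) == 0) 1 else km$survival[max(i)]
  }, numeric(1))
}
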