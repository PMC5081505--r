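#' Right-continuous step functions
#'
#' Cumulative hazard and survival estimates in this package are step
#' functions: a sorted vector of knot times, the value attained at (and
#' after) each knot, and an initial value taken before the first knot (0 for
#' a cumulative hazard, 1 for a survival function).
#'
#' @param knots Strictly increasing numeric vector of times (days).
#' @param values Numeric vector, one value per knot.
#' @param init Value before the first knot.
#' @return An object of class `icu_stepfun`.
#' @seealso [eval_stepfun()], [nelson_aalen()], [survival_function()]
#' @export
#' @examples
#' s <- icu_stepfun(c(1, 3), c(0.5, 1.25))
#' eval_stepfun(s, 0:4)  # 0 0.5 0.5 1.25 1.25
icu_stepfun <- function(knots, values, init = 0) {
  knots <- as.numeric(knots)
  values <- as.numeric(values)
  assert_that(length(knots) == length(values),
              "knots and values must have equal length")
  if (length(knots) > 1) {
    assert_that(all(diff(knots) > 0), "knots must be strictly increasing")
  }
  structure(list(knots = knots, values = values, init = init),
            class = "icu_stepfun")
}

#' Evaluate a step function
#'
#' @param sf An [icu_stepfun()].
#' @param t Numeric vector of evaluation times.
#' @return Numeric vector: `sf$init` before the first knot, otherwise the
#'   value at the largest knot `<= t` (right-continuous).
#' @export
eval_stepfun <- function(sf, t) {
  stopifnot(inherits(sf, "icu_stepfun"))
  idx <- findInterval(t, sf$knots)
  c(sf$init, sf$values)[idx + 1L]
}

#' @export
print.icu_stepfun <- function(x, ...) {
  cat("Step function with", length(x$knots), "knots, init", x$init, "\n")
  if (length(x$knots)) {
    print(data.frame(t = x$knots, value = x$values), row.names = FALSE)
  }
  invisible(x)
}

#' Nelson-Aalen cumulative hazard estimator
#'
#' Nonparametric estimate of the cumulative hazard from right-censored
#' observations: at each distinct event time the estimate increases by
#' (number of events at that time) / (number still at risk). Censored cases
#' leave the risk set after their censoring time.
#'
#' @param times Non-negative observed times (days).
#' @param events Logical (or 0/1) event indicators; `FALSE` = right-censored.
#' @return An [icu_stepfun()] cumulative hazard (non-decreasing, 0 before the
#'   first event time). With no events the function is identically 0.
#' @export
#' @examples
#' na <- nelson_aalen(c(1, 2, 2, 4), c(TRUE, TRUE, TRUE, TRUE))
#' eval_stepfun(na, c(1, 2, 4))  # 0.25, 0.25 + 2/3, 0.25 + 2/3 + 1
nelson_aalen <- function(times, events) {
  assert_that(length(times) > 0, "at least one observation is required")
  assert_that(length(times) == length(events), "times and events lengths differ")
  assert_that(all(times >= 0), "times must be non-negative")
  events <- as.logical(events)
  etimes <- sort(unique(times[events]))
  if (length(etimes) == 0) return(icu_stepfun(numeric(0), numeric(0)))
  d <- vapply(etimes, function(tt) sum(times == tt & events), numeric(1))
  n_risk <- vapply(etimes, function(tt) sum(times >= tt), numeric(1))
  icu_stepfun(etimes, cumsum(d / n_risk))
}

#' Survival function from a cumulative hazard
#'
#' Transforms a cumulative hazard step function H into the survival function
#' S(t) = exp(-H(t)): the probability that the patient is still in the ICU at
#' time t. S starts at 1 before the first event time, is non-increasing, and
#' lies in (0, 1].
#'
#' @param chf An [icu_stepfun()] with non-decreasing, non-negative values.
#' @return An [icu_stepfun()] survival function.
#' @export
#' @examples
#' survival_function(nelson_aalen(c(1, 2), c(TRUE, TRUE)))
survival_function <- function(chf) {
  stopifnot(inherits(chf, "icu_stepfun"))
  assert_that(all(chf$values >= 0) &&
                (length(chf$values) < 2 || all(diff(chf$values) >= -1e-12)),
              "cumulative hazard must be non-negative and non-decreasing")
  icu_stepfun(chf$knots, exp(-chf$values), init = exp(-chf$init))
}

#' Two-sample log-rank statistic
#'
#' Standardised log-rank statistic comparing the survival experience of two
#' groups; the node-splitting criterion of the survival forest. Positive
#' values indicate fewer events than expected (longer survival) in the group
#' flagged by `left_mask`; the sign flips when the labels swap, so splits
#' are selected on the absolute value.
#'
#' @param times Observed times.
#' @param events Event indicators (`FALSE` = censored).
#' @param left_mask Logical vector assigning each case to the first group.
#' @return The standardised statistic (approximately standard normal under
#'   equal survival).
#' @export
log_rank_statistic <- function(times, events, left_mask) {
  events <- as.logical(events)
  left_mask <- as.logical(left_mask)
  assert_that(length(times) == length(events) && length(times) == length(left_mask),
              "times, events and left_mask must have equal length")
  assert_that(any(left_mask) && any(!left_mask), "both groups must be non-empty")
  assert_that(any(events), "log-rank statistic undefined without events")
  etimes <- sort(unique(times[events]))
  d <- vapply(etimes, function(tt) sum(events & times == tt), numeric(1))
  d_l <- vapply(etimes, function(tt) sum(events & left_mask & times == tt), numeric(1))
  n <- vapply(etimes, function(tt) sum(times >= tt), numeric(1))
  n_l <- vapply(etimes, function(tt) sum(left_mask & times >= tt), numeric(1))
  u <- sum(d_l - d * n_l / n)
  keep <- n > 1
  v <- sum((d * (n_l / n) * (1 - n_l / n) * (n - d) / (n - 1))[keep])
  assert_that(v > 0, "log-rank variance is zero; statistic undefined")
  # expected-minus-observed convention: fewer events in group => positive
  -u / sqrt(v)
}
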