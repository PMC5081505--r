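#' Occupancy curves
#'
#' An occupancy curve gives the (expected or actual) number of occupied ICU
#' beds for a fixed group of current patients on an integer day grid
#' 0..horizon, where day 0 is the prediction morning. No new admissions are
#' considered, so every curve is non-increasing.
#'
#' @param beds Numeric vector of bed counts, one per day 0..horizon.
#' @param kind Label: `"expected"` or `"actual"`.
#' @return An object of class `icu_occupancy`, a data-frame-like list with
#'   columns `day` and `beds`.
#' @keywords internal
new_occupancy_curve <- function(beds, kind = "expected") {
  structure(list(day = seq_along(beds) - 1L, beds = as.numeric(beds),
                 kind = kind),
            class = "icu_occupancy")
}

#' @export
print.icu_occupancy <- function(x, ...) {
  cat(sprintf("%s occupancy over days 0..%d:\n", x$kind, max(x$day)))
  print(data.frame(day = x$day, beds = round(x$beds, 3)), row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.icu_occupancy <- function(x, ...) {
  data.frame(day = x$day, beds = x$beds)
}

#' Expected occupancy from a survival forest
#'
#' For each patient in the group the forest's ensemble cumulative hazard is
#' turned into a survival function S(t) = exp(-H(t)) -- the probability the
#' patient still occupies a bed t days after the prediction morning -- and
#' the survival functions are summed at each day to give the expected number
#' of occupied beds.
#'
#' @param model A fitted [fit_rsf()] forest.
#' @param group Data frame or matrix of predictor rows, one per patient
#'   currently admitted.
#' @param horizon Last day of the grid (default 10).
#' @return An `icu_occupancy` curve over days `0..horizon`.
#' @export
predict_occupancy_rsf <- function(model, group, horizon = 10) {
  stopifnot(inherits(model, "icu_rsf"))
  X <- as_feature_matrix(model, group)
  assert_that(nrow(X) >= 1, "group is empty")
  S <- predict(model, X, times = 0:horizon, type = "survival")
  new_occupancy_curve(colSums(S), kind = "expected")
}

#' Occupancy implied by point predictions of remaining stay
#'
#' Scores individual-level predictors (the regression forest, the resampling
#' baseline) on the same footing as the survival forest: a patient with
#' predicted remaining stay L occupies a bed on days `0 .. ceiling(L) - 1`,
#' i.e. the day-t count is the number of patients with prediction `> t`.
#'
#' @param predicted_los Numeric vector of predicted remaining stays (days,
#'   `>= 0`), one per patient.
#' @param horizon Last day of the grid (default 10).
#' @return An `icu_occupancy` curve over days `0..horizon`.
#' @export
predict_occupancy_pointwise <- function(predicted_los, horizon = 10) {
  assert_that(all(predicted_los >= 0), "predicted remaining stays must be >= 0")
  beds <- vapply(0:horizon, function(t) sum(predicted_los > t), numeric(1))
  new_occupancy_curve(beds, kind = "expected")
}

#' Actual occupancy of a patient group
#'
#' Counts, for each day of the grid, the patients whose actual remaining
#' stay (to physical ICU exit, whether discharge or death) exceeds that day.
#'
#' @param actual_remaining Numeric vector of actual remaining stays (days).
#' @param horizon Last day of the grid (default 10).
#' @return An `icu_occupancy` curve over days `0..horizon`.
#' @export
real_occupancy <- function(actual_remaining, horizon = 10) {
  assert_that(all(actual_remaining >= 0), "remaining stays must be >= 0")
  beds <- vapply(0:horizon, function(t) sum(actual_remaining > t), numeric(1))
  new_occupancy_curve(beds, kind = "actual")
}
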