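#' SOFA organ-failure subscores
#'
#' The Sequential Organ Failure Assessment (SOFA) score grades six organ
#' systems (coagulation, renal, liver, central nervous system, respiration,
#' cardiovascular) on an integer scale 0 (normal) to 4 (severe failure) from
#' the worst values of routine clinical measurements over a 24 h window. The
#' total score is the sum of the six subscores, 0-24.
#'
#' All subscore functions are vectorised and treat `NA` as "not monitored",
#' which maps to subscore 0: in routine ICU practice a channel is left
#' unmonitored when the clinician judges the organ healthy. Overlapping
#' cutpoints are resolved most-severe-first (4 down to 0), the standard SOFA
#' convention; drug-dose intervals are half-open `(a, b]`.
#'
#' @param thrombocytes Minimum platelet count, in 1000/uL.
#' @param creatinine Maximum serum creatinine, mg/dL.
#' @param urine 24 h urine output, mL.
#' @param bilirubin Maximum serum bilirubin, mg/dL.
#' @param gcs Minimum Glasgow coma score, integer 3-15. For sedated patients
#'   the caller supplies the last known pre-sedation value.
#' @param pf_ratio Minimum PaO2/FiO2 ratio, mm Hg.
#' @param ventilated Logical, mechanical ventilation in the last 24 h.
#'   `NA` is treated as not ventilated.
#' @param map Mean arterial pressure, mm Hg.
#' @param dopamine,dobutamine,epinephrine,norepinephrine Maximum administered
#'   dose, ug/kg/min.
#' @return Integer vector of subscores in `0:4`.
#' @name sofa_subscores
#' @examples
#' sofa_coagulation(c(15, 151, NA))   # 4, 0, 0
#' sofa_respiratory(150, ventilated = TRUE)  # 3
NULL

#' @rdname sofa_subscores
#' @export
sofa_coagulation <- function(thrombocytes) {
  assert_that(all(thrombocytes >= 0, na.rm = TRUE),
              "thrombocyte count must be non-negative")
  x <- thrombocytes
  score <- integer(length(x))
  score[!is.na(x) & x <= 150] <- 1L
  score[!is.na(x) & x <= 100] <- 2L
  score[!is.na(x) & x <= 50] <- 3L
  score[!is.na(x) & x <= 20] <- 4L
  score
}

#' @rdname sofa_subscores
#' @export
sofa_renal <- function(creatinine, urine = NA_real_) {
  assert_that(all(creatinine >= 0, na.rm = TRUE), "creatinine must be non-negative")
  assert_that(all(urine >= 0, na.rm = TRUE), "urine volume must be non-negative")
  n <- max(length(creatinine), length(urine))
  a <- rep_len(creatinine, n)
  b <- rep_len(urine, n)
  # absent channels never trigger a branch
  a_ge <- function(cut) !is.na(a) & a >= cut
  b_lt <- function(cut) !is.na(b) & b < cut
  ifelse(a_ge(4.9) | b_lt(200), 4L,
    ifelse(a_ge(3.4) | b_lt(500), 3L,
      ifelse(a_ge(1.9), 2L,
        ifelse(a_ge(1.2), 1L, 0L))))
}

#' @rdname sofa_subscores
#' @export
sofa_liver <- function(bilirubin) {
  assert_that(all(bilirubin >= 0, na.rm = TRUE), "bilirubin must be non-negative")
  x <- bilirubin
  score <- integer(length(x))
  score[!is.na(x) & x >= 1.2] <- 1L
  score[!is.na(x) & x >= 2] <- 2L
  score[!is.na(x) & x >= 6] <- 3L
  score[!is.na(x) & x >= 12] <- 4L
  score
}

#' @rdname sofa_subscores
#' @export
sofa_cns <- function(gcs) {
  ok <- is.na(gcs) | (gcs >= 3 & gcs <= 15)
  assert_that(all(ok), "Glasgow coma score must lie in [3, 15]")
  x <- gcs
  score <- integer(length(x))
  score[!is.na(x) & x <= 14] <- 1L
  score[!is.na(x) & x <= 12] <- 2L
  score[!is.na(x) & x <= 9] <- 3L
  score[!is.na(x) & x <= 6] <- 4L
  score
}

#' @rdname sofa_subscores
#' @export
sofa_respiratory <- function(pf_ratio, ventilated = FALSE) {
  assert_that(all(pf_ratio > 0, na.rm = TRUE), "PaO2/FiO2 ratio must be positive")
  n <- max(length(pf_ratio), length(ventilated))
  x <- rep_len(pf_ratio, n)
  v <- rep_len(ventilated, n)
  v[is.na(v)] <- FALSE
  known <- !is.na(x)
  # a low ratio without ventilation falls through to the unventilated branches
  ifelse(known & x <= 100 & v, 4L,
    ifelse(known & x <= 200 & v, 3L,
      ifelse(known & x <= 300, 2L,
        ifelse(known & x <= 400, 1L, 0L))))
}

#' @rdname sofa_subscores
#' @export
sofa_cardiovascular <- function(map = NA_real_, dopamine = NA_real_,
                                dobutamine = NA_real_, epinephrine = NA_real_,
                                norepinephrine = NA_real_) {
  for (d in list(dopamine, dobutamine, epinephrine, norepinephrine)) {
    assert_that(all(d >= 0, na.rm = TRUE), "drug doses must be non-negative")
  }
  n <- max(length(map), length(dopamine), length(dobutamine),
           length(epinephrine), length(norepinephrine))
  map <- rep_len(map, n); dop <- rep_len(dopamine, n)
  dobu <- rep_len(dobutamine, n); epi <- rep_len(epinephrine, n)
  nor <- rep_len(norepinephrine, n)
  gt <- function(x, cut) !is.na(x) & x > cut
  ifelse(gt(dop, 15) | gt(epi, 0.1) | gt(nor, 0.1), 4L,
    ifelse(gt(dop, 5) | gt(epi, 0) | gt(nor, 0), 3L,
      ifelse(gt(dop, 0) | gt(dobu, 0), 2L,
        ifelse(!is.na(map) & map < 70, 1L, 0L))))
}

#' Score one or more patient-days
#'
#' Applies the six SOFA subscore mappings to rows of raw daily physiology and
#' returns the subscores plus their sum.
#'
#' @param physiology A data frame with (a subset of) the columns
#'   `thrombocytes_min`, `creatinine_max`, `urine_sum`, `bilirubin_max`,
#'   `gcs_min`, `pf_ratio_min`, `ventilated`, `map_mean`, `dopamine_max`,
#'   `dobutamine_max`, `epinephrine_max`, `norepinephrine_max`. Missing
#'   columns behave like all-`NA` (not monitored). Identifier columns
#'   `patient_id` and `day` are carried through when present.
#' @return A data frame with integer columns `coag`, `renal`, `liver`, `cns`,
#'   `resp`, `cardio` and `total` (= their sum), one row per input row.
#' @export
#' @examples
#' score_day(data.frame(thrombocytes_min = 40, gcs_min = 8,
#'                      pf_ratio_min = 150, ventilated = TRUE))
score_day <- function(physiology) {
  assert_that(is.data.frame(physiology), "physiology must be a data frame")
  n <- nrow(physiology)
  col <- function(name, default = NA_real_) {
    if (name %in% names(physiology)) physiology[[name]] else rep(default, n)
  }
  out <- data.frame(
    coag = sofa_coagulation(col("thrombocytes_min")),
    renal = sofa_renal(col("creatinine_max"), col("urine_sum")),
    liver = sofa_liver(col("bilirubin_max")),
    cns = sofa_cns(col("gcs_min")),
    resp = sofa_respiratory(col("pf_ratio_min"), col("ventilated", NA)),
    cardio = sofa_cardiovascular(col("map_mean"), col("dopamine_max"),
                                 col("dobutamine_max"), col("epinephrine_max"),
                                 col("norepinephrine_max"))
  )
  out$total <- out$coag + out$renal + out$liver + out$cns + out$resp + out$cardio
  id_cols <- intersect(c("patient_id", "day"), names(physiology))
  if (length(id_cols)) out <- cbind(physiology[, id_cols, drop = FALSE], out)
  rownames(out) <- NULL
  out
}

#' Score every patient-day of a cohort
#'
#' @param cohort An `icu_cohort` (see [generate_cohort()]) or a physiology
#'   data frame as accepted by [score_day()].
#' @return A data frame of daily SOFA subscores and totals with `patient_id`
#'   and `day` columns.
#' @export
score_cohort <- function(cohort) {
  phys <- if (inherits(cohort, "icu_cohort")) cohort$physiology else cohort
  assert_that(all(c("patient_id", "day") %in% names(phys)),
              "physiology table must carry patient_id and day columns")
  score_day(phys)
}
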