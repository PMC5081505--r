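#' Canonical feature names of the supervised dataset
#'
#' 19 predictors: the six SOFA subscores for each of the three days
#' preceding the prediction morning (suffix `_d1` = three days back, `_d3` =
#' the most recent day) plus the number of days already admitted.
#'
#' @return Character vector of length 19 in canonical column order.
#' @export
sofa_feature_names <- function() {
  organs <- c("coag", "renal", "liver", "cns", "resp", "cardio")
  c(as.vector(t(outer(organs, 1:3,
                      function(o, d) sprintf("sofa_%s_d%d", o, d)))),
    "days_admitted")
}

#' Apply the cohort inclusion filters
#'
#' Keeps stays with a length of stay of 3 to 16 days. Very short stays are
#' dominated by uneventful recoveries and leave fewer than three days of
#' history for the sliding window; very long stays are the province of
#' prolonged-stay models.
#'
#' @param cohort An `icu_cohort` or a `stays` data frame with columns
#'   `patient_id`, `los`, `exit_type`.
#' @return A list with `stays` (the kept rows) and `filter_log`, a data
#'   frame of counts removed per rule plus the kept count.
#' @export
#' @examples
#' stays <- data.frame(patient_id = letters[1:4], los = c(2, 3, 16, 17),
#'                     exit_type = "discharge")
#' filter_cohort(stays)$stays$los  # 3 16
filter_cohort <- function(cohort) {
  stays <- if (inherits(cohort, "icu_cohort")) cohort$stays else cohort
  if (is.null(stays)) {
    stays <- data.frame(patient_id = character(0), los = integer(0),
                        exit_type = character(0))
  }
  short <- stays$los < 3
  long <- stays$los > 16
  kept <- stays[!short & !long, , drop = FALSE]
  rownames(kept) <- NULL
  log <- data.frame(
    rule = c("los_under_3", "los_over_16", "kept"),
    count = c(sum(short), sum(long), nrow(kept))
  )
  list(stays = kept, filter_log = log)
}

#' Sliding-window dataset entries for one stay
#'
#' Creates one entry per prediction morning, starting at the morning of day
#' 4 and ending at the last morning of the stay: the entry at `index_day`
#' carries the six SOFA subscores of the three preceding days (18
#' predictors), the days already admitted (`index_day - 1`), the remaining
#' length of stay `los - index_day + 1` measured morning-to-morning, and the
#' event flag (`TRUE` for discharge; death is right censoring). A stay of
#' `los` days therefore yields `los - 3` entries with remaining stays
#' `los - 3, ..., 1`.
#'
#' @param stay One-row data frame with `patient_id`, `los`, `exit_type`.
#' @param scored Data frame of daily SOFA subscores for this patient
#'   (columns `day`, `coag`, `renal`, `liver`, `cns`, `resp`, `cardio`),
#'   covering days `1..los`.
#' @return Data frame of entries (possibly empty), columns `patient_id`,
#'   `index_day`, the 19 features of [sofa_feature_names()],
#'   `remaining_los`, `event`.
#' @export
build_entries <- function(stay, scored) {
  assert_that(nrow(stay) == 1, "stay must be a single row")
  los <- stay$los
  feats <- sofa_feature_names()
  empty <- function() {
    out <- data.frame(patient_id = character(0), index_day = integer(0))
    for (f in feats) out[[f]] <- numeric(0)
    out$remaining_los <- integer(0)
    out$event <- logical(0)
    out
  }
  if (los < 4) return(empty())
  scored <- scored[order(scored$day), , drop = FALSE]
  assert_that(all(seq_len(los) %in% scored$day),
              "scored days 1..los missing for patient ", stay$patient_id)
  organs <- c("coag", "renal", "liver", "cns", "resp", "cardio")
  entries <- lapply(4:los, function(index_day) {
    window <- scored[match((index_day - 3):(index_day - 1), scored$day), ]
    row <- data.frame(patient_id = stay$patient_id, index_day = index_day)
    for (o in organs) {
      for (d in 1:3) row[[sprintf("sofa_%s_d%d", o, d)]] <- window[[o]][d]
    }
    row$days_admitted <- index_day - 1
    row$remaining_los <- los - index_day + 1
    row$event <- stay$exit_type == "discharge"
    row
  })
  out <- do.call(rbind, entries)
  out[, c("patient_id", "index_day", feats, "remaining_los", "event")]
}

#' Assemble the supervised dataset
#'
#' Filters the cohort to stays of 3-16 days, applies the sliding-window
#' construction to every kept stay, and concatenates the entries.
#'
#' @param cohort An `icu_cohort` or a `stays` data frame.
#' @param scored Data frame of daily SOFA subscores for the whole cohort
#'   (from [score_cohort()]), with `patient_id` and `day` columns.
#' @return A data frame of entries with attributes `feature_names` (the 19
#'   canonical labels) and `provenance` (the filter log plus entry counts).
#' @export
#' @examples
#' cohort <- generate_cohort(simulation_config(n_patients = 30, seed = 7))
#' data <- assemble_dataset(cohort, score_cohort(cohort))
#' ncol(data[attr(data, "feature_names")])  # 19
assemble_dataset <- function(cohort, scored) {
  filt <- filter_cohort(cohort)
  stays <- filt$stays
  pieces <- lapply(seq_len(nrow(stays)), function(i) {
    pid <- stays$patient_id[i]
    build_entries(stays[i, , drop = FALSE],
                  scored[scored$patient_id == pid, , drop = FALSE])
  })
  out <- if (length(pieces)) do.call(rbind, pieces) else build_entries(
    data.frame(patient_id = "none", los = 3L, exit_type = "discharge"),
    data.frame(day = 1:3, coag = 0, renal = 0, liver = 0, cns = 0,
               resp = 0, cardio = 0))
  rownames(out) <- NULL
  key <- paste(out$patient_id, out$index_day)
  assert_that(!anyDuplicated(key), "duplicate (patient_id, index_day) entries")
  attr(out, "feature_names") <- sofa_feature_names()
  attr(out, "provenance") <- list(filter_log = filt$filter_log,
                                  n_entries = nrow(out),
                                  n_patients = length(unique(out$patient_id)))
  out
}
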