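fake_scored <- function(los, pid = "p1") {
  data.frame(patient_id = pid, day = seq_len(los),
             coag = seq_len(los) %% 5, renal = (seq_len(los) + 1) %% 5,
             liver = 0L, cns = 1L, resp = 2L, cardio = 0L)
}

test_that("cohort filter keeps stays of 3 to 16 days and logs the counts", {
  stays <- data.frame(patient_id = c("a", "b", "c", "d"),
                      los = c(2L, 3L, 16L, 17L),
                      exit_type = "discharge")
  f <- filter_cohort(stays)
  expect_identical(f$stays$los, c(3L, 16L))
  expect_identical(f$filter_log$count,
                   c(1L, 1L, 2L))

  empty <- filter_cohort(data.frame(patient_id = character(0),
                                    los = integer(0),
                                    exit_type = character(0)))
  expect_identical(nrow(empty$stays), 0L)
  expect_true(all(empty$filter_log$count == 0L))

  cohort <- generate_cohort(simulation_config(n_patients = 300, seed = 3))
  f <- filter_cohort(cohort)
  expect_identical(sum(f$filter_log$count), 300L)
})

test_that("sliding window yields los - 3 entries with decreasing targets", {
  stay <- function(los, exit = "discharge") {
    data.frame(patient_id = "p1", los = los, exit_type = exit)
  }
  # los = 3: the only morning with three days of history is discharge morning
  expect_identical(nrow(build_entries(stay(3L), fake_scored(3))), 0L)
  e4 <- build_entries(stay(4L), fake_scored(4))
  expect_identical(nrow(e4), 1L)
  expect_identical(e4$index_day, 4L)
  expect_equal(e4$remaining_los, 1)

  e6 <- build_entries(stay(6L), fake_scored(6))
  expect_identical(e6$index_day, 4:6)
  expect_equal(e6$remaining_los, c(3, 2, 1))
  expect_equal(diff(e6$remaining_los), c(-1, -1))
  # window content: entry at day 4 sees days 1..3, most recent is d3
  expect_equal(e6$sofa_coag_d3[1], fake_scored(6)$coag[3])
  expect_equal(e6$sofa_coag_d1[1], fake_scored(6)$coag[1])
  expect_equal(e6$days_admitted, e6$index_day - 1)

  # death censors every entry of the stay
  e_death <- build_entries(stay(6L, "death"), fake_scored(6))
  expect_identical(e_death$event, rep(FALSE, 3))
  expect_error(build_entries(stay(6L), fake_scored(4)), "missing")
})

test_that("assemble_dataset produces the canonical 19-predictor table", {
  stays <- rbind(data.frame(patient_id = "a", los = 5L,
                            exit_type = "discharge"),
                 data.frame(patient_id = "b", los = 4L, exit_type = "death"))
  scored <- rbind(fake_scored(5, "a"), fake_scored(4, "b"))
  cohort <- structure(list(stays = stays, physiology = NULL), class = "icu_cohort")
  data <- assemble_dataset(cohort, scored)
  expect_identical(nrow(data), 3L)  # (5-3) + (4-3)
  feats <- attr(data, "feature_names")
  expect_length(feats, 19L)
  expect_identical(feats, sofa_feature_names())
  expect_true(all(feats %in% names(data)))
  expect_identical(names(data),
                   c("patient_id", "index_day", feats, "remaining_los",
                     "event"))
  expect_true(all(as.matrix(data[, feats[1:18]]) >= 0 &
                    as.matrix(data[, feats[1:18]]) <= 4))
})

test_that("simulated datasets satisfy the window invariants", {
  data <- small_pipeline_dataset(n_patients = 200, seed = 17)
  expect_true(all(data$days_admitted == data$index_day - 1))
  expect_true(all(data$remaining_los >= 1))
  counts <- table(data$patient_id)
  cohort_los <- data$index_day + data$remaining_los - 1
  for (pid in names(counts)[1:10]) {
    rows <- data[data$patient_id == pid, ]
    los <- unique(rows$index_day + rows$remaining_los - 1)
    expect_length(los, 1L)
    expect_identical(unname(counts[pid]), as.integer(los - 3))
    expect_equal(diff(rows$remaining_los[order(rows$index_day)]),
                 rep(-1, nrow(rows) - 1))
  }
})
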