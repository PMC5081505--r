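test_that("coagulation subscore follows the thrombocyte thresholds", {
  expect_identical(sofa_coagulation(c(15, 20, 21, 50, 51, 100, 101, 150, 151)),
                   c(4L, 4L, 3L, 3L, 2L, 2L, 1L, 1L, 0L))
  expect_identical(sofa_coagulation(NA), 0L)
  expect_error(sofa_coagulation(-1), "non-negative")
})

test_that("renal subscore combines creatinine and urine most-severe-first", {
  expect_identical(sofa_renal(5.0, 2000), 4L)
  expect_identical(sofa_renal(2.5, 1500), 2L)
  expect_identical(sofa_renal(0.8, 2000), 0L)
  # urine criteria alone can trigger the 3 and 4 branches
  expect_identical(sofa_renal(NA, 150), 4L)
  expect_identical(sofa_renal(0.5, 450), 3L)
  expect_identical(sofa_renal(c(1.2, 1.9, 3.4, 4.9)), c(1L, 2L, 3L, 4L))
  expect_identical(sofa_renal(NA, NA), 0L)
  expect_error(sofa_renal(-0.1), "non-negative")
})

test_that("liver subscore follows the bilirubin thresholds", {
  expect_identical(sofa_liver(c(13, 12, 6, 2.0, 1.2, 0.8, 1.19)),
                   c(4L, 4L, 3L, 2L, 1L, 0L, 0L))
  expect_identical(sofa_liver(NA), 0L)
})

test_that("cns subscore follows the Glasgow coma scale bands", {
  expect_identical(sofa_cns(c(15, 14, 13, 12, 10, 9, 8, 7, 6, 3)),
                   c(0L, 1L, 1L, 2L, 2L, 3L, 3L, 3L, 4L, 4L))
  expect_identical(sofa_cns(8), 3L)
  expect_identical(sofa_cns(NA), 0L)
  expect_error(sofa_cns(2), "\\[3, 15\\]")
  expect_error(sofa_cns(16), "\\[3, 15\\]")
})

test_that("respiratory subscore needs ventilation for the severe branches", {
  expect_identical(sofa_respiratory(150, TRUE), 3L)
  expect_identical(sofa_respiratory(90, TRUE), 4L)
  # low PF without ventilation falls through to the unventilated branches
  expect_identical(sofa_respiratory(150, FALSE), 2L)
  expect_identical(sofa_respiratory(90, FALSE), 2L)
  expect_identical(sofa_respiratory(c(250, 301, 350, 401, 450), FALSE),
                   c(2L, 1L, 1L, 0L, 0L))
  expect_identical(sofa_respiratory(NA, TRUE), 0L)
  expect_error(sofa_respiratory(0), "positive")
})

test_that("cardiovascular subscore ranks drugs above hypotension", {
  expect_identical(sofa_cardiovascular(dopamine = 20), 4L)
  expect_identical(sofa_cardiovascular(map = 80, dobutamine = 5), 2L)
  expect_identical(sofa_cardiovascular(map = 65), 1L)
  expect_identical(sofa_cardiovascular(map = 70), 0L)
  # half-open dose intervals
  expect_identical(sofa_cardiovascular(dopamine = c(5, 5.1, 15, 15.1)),
                   c(2L, 3L, 3L, 4L))
  expect_identical(sofa_cardiovascular(epinephrine = c(0.05, 0.1, 0.11)),
                   c(3L, 3L, 4L))
  expect_identical(sofa_cardiovascular(norepinephrine = 0.2, map = 90), 4L)
  expect_identical(sofa_cardiovascular(), 0L)
  expect_error(sofa_cardiovascular(dopamine = -2), "non-negative")
})

test_that("score_day sums the six subscores into the total", {
  # all channels absent
  empty <- score_day(data.frame(thrombocytes_min = NA_real_))
  expect_identical(empty$total, 0L)
  # worst case on every organ system
  worst <- score_day(data.frame(
    thrombocytes_min = 10, creatinine_max = 6, bilirubin_max = 15,
    gcs_min = 3, pf_ratio_min = 50, ventilated = TRUE, dopamine_max = 20))
  expect_identical(worst$total, 24L)
  expect_true(all(worst[, c("coag", "renal", "liver", "cns", "resp",
                            "cardio")] == 4L))
  # healthiest value on every channel
  zero <- score_day(data.frame(
    thrombocytes_min = 151, creatinine_max = 0.8, urine_sum = 2000,
    bilirubin_max = 0.8, gcs_min = 15, pf_ratio_min = 450,
    ventilated = FALSE, map_mean = 80))
  expect_identical(zero$total, 0L)
})

test_that("subscores stay in 0..4 and respond monotonically to severity", {
  set.seed(42)
  n <- 500
  phys <- data.frame(
    thrombocytes_min = runif(n, 0, 400),
    creatinine_max = runif(n, 0, 8),
    urine_sum = runif(n, 0, 4000),
    bilirubin_max = runif(n, 0, 20),
    gcs_min = sample(3:15, n, TRUE),
    pf_ratio_min = runif(n, 10, 600),
    ventilated = runif(n) < 0.5,
    map_mean = runif(n, 30, 130),
    dopamine_max = runif(n, 0, 25) * rbinom(n, 1, 0.5),
    dobutamine_max = runif(n, 0, 10) * rbinom(n, 1, 0.3),
    epinephrine_max = runif(n, 0, 0.3) * rbinom(n, 1, 0.3),
    norepinephrine_max = runif(n, 0, 0.3) * rbinom(n, 1, 0.3)
  )
  scored <- score_day(phys)
  sub <- scored[, c("coag", "renal", "liver", "cns", "resp", "cardio")]
  expect_true(all(sub >= 0 & sub <= 4))
  expect_true(all(scored$total == rowSums(sub)))
  expect_true(all(scored$total >= 0 & scored$total <= 24))

  # worsening any single channel never lowers its subscore
  expect_true(all(sofa_coagulation(pmax(phys$thrombocytes_min - 30, 0)) >=
                    scored$coag))
  expect_true(all(sofa_liver(phys$bilirubin_max + 2) >= scored$liver))
  expect_true(all(sofa_renal(phys$creatinine_max + 1, phys$urine_sum) >=
                    scored$renal))
  expect_true(all(sofa_renal(phys$creatinine_max, pmax(phys$urine_sum - 400, 0)) >=
                    scored$renal))
  expect_true(all(sofa_cns(pmax(phys$gcs_min - 2, 3)) >= scored$cns))
  expect_true(all(sofa_respiratory(pmax(phys$pf_ratio_min - 50, 1),
                                   phys$ventilated) >= scored$resp))
  expect_true(all(sofa_cardiovascular(phys$map_mean - 10, phys$dopamine_max,
                                      phys$dobutamine_max, phys$epinephrine_max,
                                      phys$norepinephrine_max) >= scored$cardio))
  expect_true(all(sofa_cardiovascular(phys$map_mean, phys$dopamine_max + 3,
                                      phys$dobutamine_max, phys$epinephrine_max,
                                      phys$norepinephrine_max) >= scored$cardio))
})
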