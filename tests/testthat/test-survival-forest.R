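test_that("an unsplit single tree reproduces the cohort Nelson-Aalen estimator", {
  d <- random_surv_sample(30, 1)
  data <- data.frame(x = runif(30), remaining_los = d$time, event = d$event)
  fit <- fit_rsf(data, rsf_params(n_trees = 1, mtry = 1, min_deaths = 1000,
                                  seed = 2, bootstrap = FALSE))
  chf <- ensemble_chf(fit, 0.5)
  expect_equal(eval_stepfun(chf, 0:10),
               brute_nelson_aalen(d$time, d$event, 0:10))
  # unsplit single-node forest: survival curve matches exp(-NA) everywhere
  s <- predict(fit, data.frame(x = 0.1), times = 0:10, type = "survival")
  expect_equal(as.numeric(s),
               exp(-brute_nelson_aalen(d$time, d$event, 0:10)))
})

test_that("forest fitting is deterministic in the seed", {
  data <- strata_dataset(30, seed = 4)
  p <- rsf_params(n_trees = 8, seed = 11)
  f1 <- fit_rsf(data, p)
  f2 <- fit_rsf(data, p)
  expect_identical(f1$trees, f2$trees)
  expect_identical(f1$inbag, f2$inbag)
  f3 <- fit_rsf(data, rsf_params(n_trees = 8, seed = 12))
  expect_false(identical(f1$trees, f3$trees))
})

test_that("a perfectly separating predictor is chosen at the root", {
  data <- strata_dataset(40, seed = 6)
  fit <- fit_rsf(data, rsf_params(n_trees = 25, mtry = 2, seed = 8))
  root_vars <- vapply(fit$trees, function(tr) tr$split_var[1], integer(1))
  expect_gte(mean(root_vars == 0L), 0.9)  # 0-based index of x1
})

test_that("row order does not change the fitted tree predictions", {
  data <- strata_dataset(30, seed = 9)
  perm <- sample(nrow(data))
  p <- rsf_params(n_trees = 1, mtry = 2, seed = 5, bootstrap = FALSE)
  f1 <- fit_rsf(data, p)
  f2 <- fit_rsf(data[perm, ], p)
  grid_x <- data.frame(x1 = rep(c(0, 1), 5), x2 = seq(0.05, 0.95, 0.1))
  expect_equal(predict(f1, grid_x), predict(f2, grid_x))
})

test_that("ensemble CHF is the average of per-tree terminal estimators", {
  data <- strata_dataset(25, seed = 10)
  fit <- fit_rsf(data, rsf_params(n_trees = 2, seed = 3))
  x <- data.frame(x1 = 0, x2 = 0.5)
  X <- as.matrix(data.frame(x1 = 0, x2 = 0.5))
  per_tree <- lapply(fit$trees, function(tr) {
    term <- predict_terminal_cpp(tr$split_var, tr$split_val, tr$left,
                                 tr$right, X)
    tr$terminal_chf[term, ]
  })
  ens <- ensemble_chf(fit, x)
  expect_equal(ens$values, (per_tree[[1]] + per_tree[[2]]) / 2)
  # B = 1: the ensemble IS the tree
  fit1 <- fit_rsf(data, rsf_params(n_trees = 1, seed = 3))
  tr <- fit1$trees[[1]]
  term <- predict_terminal_cpp(tr$split_var, tr$split_val, tr$left, tr$right, X)
  expect_equal(ensemble_chf(fit1, x)$values, as.numeric(tr$terminal_chf[term, ]))
  # CHFs never decrease
  expect_true(all(diff(ens$values) >= 0))
})

test_that("split stopping follows the unique-death rule", {
  # no events at all: fitting must refuse
  d <- data.frame(x = 1:20, remaining_los = rep(c(1, 2), 10), event = FALSE)
  expect_error(fit_rsf(d, rsf_params(n_trees = 1)), "no event")
  # d0 above the number of unique event times: every tree stays unsplit
  d$event <- TRUE
  fit <- fit_rsf(d, rsf_params(n_trees = 5, min_deaths = 3, seed = 1))
  expect_true(all(vapply(fit$trees, function(tr) tr$split_var[1], integer(1))
                  == -1L))
  # with d0 = 1 the perfectly separating split is admissible
  fit <- fit_rsf(d, rsf_params(n_trees = 5, min_deaths = 1, seed = 1))
  expect_true(any(vapply(fit$trees, function(tr) tr$split_var[1], integer(1))
                  == 0L))
})

test_that("out-of-bag concordance error behaves like 1 - Harrell C", {
  # direct check of the error functional via internal scoring
  t <- 1:20
  mort_perfect <- 21 - t  # higher mortality, shorter stay
  expect_equal(icubeds:::concordance_error(t, rep(1L, 20), mort_perfect), 0)
  expect_equal(icubeds:::concordance_error(t, rep(1L, 20), t), 1)
  set.seed(31)
  big_t <- sample(1:50, 4000, TRUE)
  rnd <- runif(4000)
  err <- icubeds:::concordance_error(big_t, rep(1L, 4000), rnd)
  expect_lt(abs(err - 0.5), 0.05)

  # on a fitted forest with signal, OOB error is clearly better than chance
  data <- strata_dataset(60, seed = 13)
  fit <- fit_rsf(data, rsf_params(n_trees = 60, seed = 14))
  err <- oob_concordance_error(fit)
  expect_gte(err, 0)
  expect_lt(err, 0.3)
  # cases never OOB must be reported
  tiny <- fit_rsf(data, rsf_params(n_trees = 1, seed = 2))
  expect_error(oob_concordance_error(tiny), "never out-of-bag")
})

test_that("ensemble survival curves start at 1 and never increase", {
  data <- small_pipeline_dataset(n_patients = 150, seed = 23)
  fit <- fit_rsf(data, rsf_params(n_trees = 30, seed = 2))
  S <- predict(fit, data[1:50, ], times = 0:12, type = "survival")
  expect_true(all(S[, 1] == 1))  # day 0 precedes the first event knot
  expect_true(all(S > 0 & S <= 1))
  expect_true(all(S[, -1] - S[, -ncol(S)] <= 1e-12))
})

test_that("pure-noise predictors do not displace the informative root split", {
  set.seed(41)
  data <- strata_dataset(40, seed = 6)
  for (j in 3:8) data[[paste0("noise", j)]] <- runif(nrow(data))
  fit <- fit_rsf(data, rsf_params(n_trees = 40, mtry = 3, seed = 15))
  root_vars <- vapply(fit$trees, function(tr) tr$split_var[1], integer(1))
  tab <- table(root_vars)
  expect_identical(names(which.max(tab)), "0")
})
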