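# Independent brute-force oracles, deliberately written without reusing any
# package internals, plus small fixture builders.

# Nelson-Aalen by direct summation over distinct event times
brute_nelson_aalen <- function(times, events, at) {
  vapply(at, function(t0) {
    total <- 0
    for (tt in sort(unique(times[events & times <= t0]))) {
      d <- sum(events & times == tt)
      at_risk <- sum(times >= tt)
      total <- total + d / at_risk
    }
    total
  }, numeric(1))
}

# standardized two-sample log-rank statistic from explicit risk tables
brute_log_rank <- function(times, events, grp1) {
  u <- 0
  v <- 0
  for (tt in sort(unique(times[events]))) {
    n <- sum(times >= tt)
    n1 <- sum(grp1 & times >= tt)
    d <- sum(events & times == tt)
    d1 <- sum(events & grp1 & times == tt)
    u <- u + (d1 - d * n1 / n)
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  -u / sqrt(v)
}

# random right-censored sample
random_surv_sample <- function(n, seed) {
  set.seed(seed)
  data.frame(time = sample(1:10, n, replace = TRUE),
             event = runif(n) < 0.7)
}

# supervised toy dataset with two separated strata on feature x1
strata_dataset <- function(n_per = 40, seed = 1) {
  set.seed(seed)
  data.frame(
    x1 = rep(c(0, 1), each = n_per),
    x2 = runif(2 * n_per),
    remaining_los = c(sample(1:3, n_per, TRUE), sample(8:12, n_per, TRUE)),
    event = TRUE
  )
}

# full 19-feature dataset in which only resp day-3 and cns day-3 carry
# signal; everything else is independent noise
signal_dataset <- function(n = 800, seed = 1, strength = 1) {
  set.seed(seed)
  feats <- sofa_feature_names()
  df <- as.data.frame(lapply(feats, function(f) sample(0:4, n, TRUE)))
  names(df) <- feats
  df$days_admitted <- sample(3:13, n, TRUE)
  base <- 1 + strength * (df$sofa_resp_d3 + df$sofa_cns_d3)
  df$remaining_los <- 1 + rpois(n, base)
  df$event <- TRUE
  attr(df, "feature_names") <- feats
  df
}

# small end-to-end simulated supervised dataset
small_pipeline_dataset <- function(n_patients = 250, seed = 5) {
  cohort <- generate_cohort(simulation_config(n_patients = n_patients,
                                              seed = seed))
  assemble_dataset(cohort, score_cohort(cohort))
}
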