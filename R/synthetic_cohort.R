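#' Synthetic ICU cohort configuration
#'
#' Parameters of the synthetic-cohort simulator. Each patient carries a
#' latent baseline severity; raw daily physiology follows mean-reverting
#' autocorrelated processes whose level scales with severity, and each
#' morning after day 1 the patient is discharged with probability
#' `plogis(discharge_base_hazard + sofa_hazard_slope * SOFA_yesterday)` and,
#' independently, dies with probability
#' `death_hazard * max(0, SOFA_yesterday - death_sofa_threshold)`. Death
#' wins when both fire; stays reaching `max_day` are truncated as
#' discharges. Discharge is the event of interest downstream and death acts
#' as right censoring.
#'
#' Defaults are chosen to yield a clinically plausible general-ICU mix:
#' median length of stay around 5-6 days, most stays within 3-16 days, an
#' in-ICU death fraction around 10 percent, and remaining stay strongly
#' dependent on recent SOFA values.
#'
#' @param n_patients Number of patients to simulate.
#' @param seed Integer seed; together with the per-patient index it fully
#'   determines the cohort.
#' @param severity_mean,severity_sd Mean and SD of the latent per-patient
#'   baseline severity (unitless; 0 is a typical stable patient, 2 severe
#'   multi-organ failure).
#' @param ar_coefficient Day-to-day autocorrelation of the latent physiology
#'   process, in `[0, 1)`.
#' @param discharge_base_hazard Intercept of the daily discharge
#'   probability on the log-odds scale, in `(0, 1)`.
#' @param sofa_hazard_slope Effect of yesterday's total SOFA on the
#'   discharge log-odds; must be `<= 0` (sicker patients stay longer).
#' @param death_hazard Daily death probability per SOFA point above
#'   `death_sofa_threshold`, in `[0, 1)`.
#' @param death_sofa_threshold Total SOFA below which the daily death
#'   probability is zero.
#' @param missing_prob Probability that a measurement channel is absent
#'   (not monitored) on a given day.
#' @param max_day Hard stop for a stay (default 60).
#' @return An object of class `icu_sim_config`.
#' @export
simulation_config <- function(n_patients, seed = 1, severity_mean = 1.2,
                              severity_sd = 0.65, ar_coefficient = 0.7,
                              discharge_base_hazard = 0.95,
                              sofa_hazard_slope = -0.3, death_hazard = 0.012,
                              death_sofa_threshold = 10, missing_prob = 0.05,
                              max_day = 60) {
  assert_that(n_patients >= 0, "n_patients must be non-negative")
  assert_that(ar_coefficient >= 0 && ar_coefficient < 1,
              "ar_coefficient must lie in [0, 1)")
  assert_that(discharge_base_hazard > 0 && discharge_base_hazard < 1,
              "discharge_base_hazard must lie in (0, 1)")
  assert_that(sofa_hazard_slope <= 0, "sofa_hazard_slope must be <= 0")
  assert_that(death_hazard >= 0 && death_hazard < 1,
              "death_hazard must lie in [0, 1)")
  assert_that(death_hazard * (24 - death_sofa_threshold) <= 1,
              "death_hazard yields a daily probability above 1 at maximal SOFA")
  assert_that(missing_prob >= 0 && missing_prob < 1,
              "missing_prob must lie in [0, 1)")
  assert_that(max_day >= 1, "max_day must be positive")
  structure(list(n_patients = as.integer(n_patients), seed = as.integer(seed),
                 severity_mean = severity_mean, severity_sd = severity_sd,
                 ar_coefficient = ar_coefficient,
                 discharge_base_hazard = discharge_base_hazard,
                 sofa_hazard_slope = sofa_hazard_slope,
                 death_hazard = death_hazard,
                 death_sofa_threshold = death_sofa_threshold,
                 missing_prob = missing_prob, max_day = as.integer(max_day)),
            class = "icu_sim_config")
}

# physiology channel names in canonical CSV order
physiology_channels <- function() {
  c("thrombocytes_min", "creatinine_max", "urine_sum", "bilirubin_max",
    "gcs_min", "sedated", "pf_ratio_min", "ventilated", "map_mean",
    "dopamine_max", "dobutamine_max", "epinephrine_max", "norepinephrine_max")
}

# one day of raw physiology from per-organ latent severities; higher latent
# value = worse organ function, mapped through monotone transforms clipped
# to physiologic ranges
raw_physiology_day <- function(s, prev_gcs, missing_prob) {
  sed <- runif(1) < plogis(1.4 * (s[["cns"]] - 2.6))
  gcs <- as.integer(round(15 - 2.2 * max(0, s[["cns"]])))
  gcs <- min(15L, max(3L, gcs))
  if (sed && !is.null(prev_gcs)) gcs <- prev_gcs  # last pre-sedation value
  vent <- runif(1) < plogis(1.6 * (s[["resp"]] - 1.5))
  s_cv <- s[["cardio"]]
  row <- list(
    thrombocytes_min = 220 * exp(-0.45 * s[["coag"]]),
    creatinine_max = 0.9 * exp(0.5 * s[["renal"]]),
    urine_sum = 2200 * exp(-0.55 * s[["renal"]]),
    bilirubin_max = 0.8 * exp(0.6 * s[["liver"]]),
    gcs_min = gcs,
    sedated = sed,
    pf_ratio_min = max(30, 460 * exp(-0.35 * s[["resp"]])),
    ventilated = vent,
    map_mean = max(35, 82 - 7 * s_cv),
    dopamine_max = if (s_cv > 1 && runif(1) < 0.25) 2 + 3 * (s_cv - 1) else 0,
    dobutamine_max = if (s_cv > 0.5 && runif(1) < 0.15) 3 else 0,
    epinephrine_max = 0,
    norepinephrine_max = max(0, 0.06 * (s_cv - 1.6))
  )
  # each channel independently unmonitored with small probability
  for (ch in setdiff(names(row), c("sedated", "ventilated"))) {
    if (runif(1) < missing_prob) row[[ch]] <- NA
  }
  row
}

simulate_patient <- function(pid, config) {
  organs <- c("coag", "renal", "liver", "cns", "resp", "cardio")
  sev <- rnorm(1, config$severity_mean, config$severity_sd)
  ar <- config$ar_coefficient
  level <- sev + rnorm(1, 0, 0.5)
  days <- list()
  prev_gcs <- NULL
  los <- config$max_day
  exit_type <- "discharge"
  for (d in seq_len(config$max_day)) {
    if (d > 1) level <- ar * level + (1 - ar) * sev + rnorm(1, 0, 0.4)
    s <- level + rnorm(length(organs), 0, 0.35)
    names(s) <- organs
    row <- raw_physiology_day(s, prev_gcs, config$missing_prob)
    prev_gcs <- if (is.na(row$gcs_min)) prev_gcs else row$gcs_min
    days[[d]] <- c(list(patient_id = pid, day = d), row)
    sofa <- sofa_coagulation(row$thrombocytes_min) +
      sofa_renal(row$creatinine_max, row$urine_sum) +
      sofa_liver(row$bilirubin_max) +
      sofa_cns(row$gcs_min) +
      sofa_respiratory(row$pf_ratio_min, row$ventilated) +
      sofa_cardiovascular(row$map_mean, row$dopamine_max, row$dobutamine_max,
                          row$epinephrine_max, row$norepinephrine_max)
    # morning after day d: death beats discharge when both fire
    p_death <- min(1, config$death_hazard *
                        max(0, sofa - config$death_sofa_threshold))
    p_dis <- plogis(config$discharge_base_hazard +
                      config$sofa_hazard_slope * sofa)
    died <- runif(1) < p_death
    discharged <- runif(1) < p_dis
    if (died) {
      los <- d; exit_type <- "death"; break
    }
    if (discharged) {
      los <- d; exit_type <- "discharge"; break
    }
  }
  phys <- do.call(rbind, lapply(days, function(x) as.data.frame(x)))
  list(physiology = phys,
       stay = data.frame(patient_id = pid, los = nrow(phys),
                         exit_type = exit_type))
}

#' Generate a synthetic ICU cohort
#'
#' Simulates `n_patients` ICU stays with raw daily physiology so that the
#' full pipeline (SOFA scoring, dataset construction, model fitting,
#' evaluation) can be exercised without hospital data. Each patient uses an
#' RNG sub-stream derived from `(seed, patient index)`, so cohorts are
#' reproducible and stable under reordering.
#'
#' @param config An [simulation_config()] object.
#' @return An object of class `icu_cohort`: a list with data frames
#'   `physiology` (one row per patient-day; `NA` = not monitored) and
#'   `stays` (`patient_id`, `los`, `exit_type`), plus the `config`.
#' @export
#' @examples
#' cohort <- generate_cohort(simulation_config(n_patients = 5, seed = 42))
#' cohort$stays
generate_cohort <- function(config) {
  stopifnot(inherits(config, "icu_sim_config"))
  if (config$n_patients == 0) {
    return(structure(list(physiology = NULL, stays = NULL, config = config,
                          patients = list()),
                     class = "icu_cohort"))
  }
  patients <- lapply(seq_len(config$n_patients), function(i) {
    pid <- sprintf("P%05d", i)
    with_seed(derive_seed(config$seed, "patient", i),
              function() simulate_patient(pid, config))
  })
  structure(list(
    physiology = do.call(rbind, lapply(patients, `[[`, "physiology")),
    stays = do.call(rbind, lapply(patients, `[[`, "stay")),
    config = config
  ), class = "icu_cohort")
}

#' @export
print.icu_cohort <- function(x, ...) {
  n <- if (is.null(x$stays)) 0 else nrow(x$stays)
  cat("Synthetic ICU cohort:", n, "stays,",
      if (is.null(x$physiology)) 0 else nrow(x$physiology), "patient-days\n")
  invisible(x)
}

#' Summarise a cohort
#'
#' @param stays An `icu_cohort` or its `stays` data frame.
#' @return A list with `n`, exit-type counts, length-of-stay quantiles, the
#'   death fraction, and the fraction of stays with length 3-16 days (the
#'   modelling window retained by [filter_cohort()]).
#' @export
cohort_summary <- function(stays) {
  if (inherits(stays, "icu_cohort")) stays <- stays$stays
  assert_that(!is.null(stays) && nrow(stays) > 0, "cohort is empty")
  los <- stays$los
  list(
    n = nrow(stays),
    exit_counts = table(factor(stays$exit_type,
                               levels = c("discharge", "death"))),
    los_quantiles = quantile(los, c(0, 0.25, 0.5, 0.75, 1)),
    death_fraction = mean(stays$exit_type == "death"),
    fraction_los_3_16 = mean(los >= 3 & los <= 16)
  )
}
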