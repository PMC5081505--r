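#' Read a run configuration from YAML
#'
#' A run configuration has a global `seed`, an `out_dir`, and optional
#' blocks `simulation`, `rsf`, `rf` and `evaluation` whose keys match the
#' arguments of [simulation_config()], [rsf_params()], [rf_params()] and
#' [eval_config()]. Unknown keys are rejected.
#'
#' @param path YAML file path.
#' @return A validated list of class `icu_run_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known_blocks <- c("seed", "out_dir", "simulation", "rsf", "rf", "evaluation",
                    "methods")
  extra <- setdiff(names(raw), known_blocks)
  assert_that(length(extra) == 0, "unknown configuration key(s): ",
              paste(extra, collapse = ", "))
  check_block <- function(block, fn, drop = character(0)) {
    if (is.null(raw[[block]])) return(list())
    allowed <- setdiff(names(formals(fn)), drop)
    bad <- setdiff(names(raw[[block]]), allowed)
    assert_that(length(bad) == 0, "unknown key(s) in '", block, "': ",
                paste(bad, collapse = ", "))
    raw[[block]]
  }
  cfg <- list(
    seed = if (is.null(raw$seed)) 1L else as.integer(raw$seed),
    out_dir = if (is.null(raw$out_dir)) "." else raw$out_dir,
    simulation = check_block("simulation", simulation_config),
    rsf = check_block("rsf", rsf_params),
    rf = check_block("rf", rf_params),
    evaluation = check_block("evaluation", eval_config),
    methods = if (is.null(raw$methods)) c("rsf", "rf", "baseline")
              else unlist(raw$methods)
  )
  assert_that(all(cfg$methods %in% c("rsf", "rf", "baseline")),
              "methods must be drawn from rsf, rf, baseline")
  structure(cfg, class = "icu_run_config")
}

#' Run the full forecasting pipeline
#'
#' Executes simulate, score, build and evaluate in sequence: generates a
#' synthetic cohort, computes daily SOFA scores, assembles the supervised
#' sliding-window dataset, cross-validates the requested methods with the
#' group-level error E, and writes every artifact (cohort and SOFA CSVs,
#' dataset CSV, report JSON) under `config$out_dir`.
#'
#' @param config An `icu_run_config` (see [read_run_config()]), or a list
#'   with the same shape.
#' @param quiet Suppress progress messages.
#' @return The `icu_eval_report`, invisibly; artifacts are on disk.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  say <- function(...) if (!quiet) message(...)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  sim_args <- config$simulation
  if (is.null(sim_args$seed)) sim_args$seed <- derive_seed(config$seed, "sim")
  sim <- do.call(simulation_config, sim_args)
  say("simulate: ", sim$n_patients, " patients (seed ", sim$seed, ")")
  cohort <- generate_cohort(sim)
  write_cohort_csv(cohort, file.path(config$out_dir, "cohort.csv"),
                   file.path(config$out_dir, "stays.csv"))

  say("score: ", nrow(cohort$physiology), " patient-days")
  scored <- score_cohort(cohort)
  write_csv_with_comment(scored, file.path(config$out_dir, "sofa.csv"),
                         provenance_line(sim))

  data <- assemble_dataset(cohort, scored)
  prov <- attr(data, "provenance")
  say("build: kept ", prov$n_patients, " patients, ", prov$n_entries,
      " entries (removed ",
      sum(prov$filter_log$count[prov$filter_log$rule != "kept"]),
      " stays by the 3-16 day filters)")
  write_dataset_csv(data, file.path(config$out_dir, "dataset.csv"),
                    config = sim)

  eval_args <- config$evaluation
  if (is.null(eval_args$seed)) eval_args$seed <- derive_seed(config$seed, "eval")
  ec <- do.call(eval_config, eval_args)
  methods <- list()
  if ("rsf" %in% config$methods) {
    methods <- c(methods, list(method_rsf(do.call(rsf_params, config$rsf))))
  }
  if ("rf" %in% config$methods) {
    methods <- c(methods, list(method_rf(do.call(rf_params, config$rf))))
  }
  if ("baseline" %in% config$methods) {
    methods <- c(methods, list(method_baseline()))
  }
  say("evaluate: ", ec$k_folds, "-fold CV of ",
      paste(config$methods, collapse = ", "))
  report <- cross_validate(data, methods, ec)
  report_path <- file.path(config$out_dir, "report.json")
  jsonlite::write_json(
    list(config_md5 = config_hash(config), seed = config$seed,
         E = as.data.frame(report$E), pairwise = report$pairwise,
         filter_log = prov$filter_log),
    report_path, digits = NA, dataframe = "columns")
  say("report written to ", report_path)
  invisible(report)
}
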