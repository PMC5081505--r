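#' @name icu_io
#' @title Readers and writers for pipeline artifacts
#'
#' @description Tabular artifacts are plain CSV (empty cell = not
#' monitored), models and evaluation reports are JSON, and run
#' configurations are YAML. Writers prepend a `#`-prefixed provenance
#' comment carrying an MD5 hash of the generating configuration; readers
#' skip comment lines.
#'
#' @param cohort,path,stays_path,data,model See the individual functions.
NULL

config_hash <- function(config) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(unclass(config), tf, auto_unbox = TRUE, digits = NA,
                       null = "null")
  unname(tools::md5sum(tf))
}

provenance_line <- function(config) {
  if (is.null(config)) return(NULL)
  paste0("# config_md5=", config_hash(config))
}

write_csv_with_comment <- function(df, path, comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(comment, con)
  write.csv(df, con, row.names = FALSE, quote = FALSE, na = "")
}

#' @rdname icu_io
#' @param phys_path,stays_path Output/input CSV paths for the physiology
#'   table (one row per patient-day) and the stays sidecar
#'   (`patient_id,los,exit_type`).
#' @export
write_cohort_csv <- function(cohort, phys_path, stays_path) {
  stopifnot(inherits(cohort, "icu_cohort"))
  comment <- provenance_line(cohort$config)
  phys <- cohort$physiology
  if (is.null(phys)) {
    cols <- rep(list(logical(0)), 2 + length(physiology_channels()))
    names(cols) <- c("patient_id", "day", physiology_channels())
    phys <- as.data.frame(cols)
  }
  write_csv_with_comment(phys[, c("patient_id", "day", physiology_channels())],
                         phys_path, comment)
  stays <- cohort$stays
  if (is.null(stays)) {
    stays <- data.frame(patient_id = character(0), los = integer(0),
                        exit_type = character(0))
  }
  write_csv_with_comment(stays, stays_path, comment)
  invisible(c(phys_path, stays_path))
}

#' @rdname icu_io
#' @export
read_cohort_csv <- function(phys_path, stays_path) {
  phys <- read.csv(phys_path, comment.char = "#", stringsAsFactors = FALSE)
  required <- c("patient_id", "day", physiology_channels())
  missing_cols <- setdiff(required, names(phys))
  assert_that(length(missing_cols) == 0, "cohort CSV is missing column(s): ",
              paste(missing_cols, collapse = ", "))
  for (ch in c("sedated", "ventilated")) phys[[ch]] <- as.logical(phys[[ch]])
  numeric_cols <- setdiff(physiology_channels(), c("sedated", "ventilated"))
  for (ch in numeric_cols) {
    v <- phys[[ch]]
    assert_that(is.numeric(v) || all(is.na(v)),
                "non-numeric values in column ", ch)
    bad <- which(!is.na(v) & v < 0)
    assert_that(length(bad) == 0, "negative value in column ", ch,
                " at row ", if (length(bad)) bad[1] else 0)
  }
  # days must be consecutive from 1 within each patient
  by_pat <- split(phys$day, phys$patient_id)
  for (pid in names(by_pat)) {
    d <- sort(by_pat[[pid]])
    assert_that(identical(as.integer(d), seq_len(length(d))),
                "days for patient ", pid, " are not consecutive from 1")
  }
  stays <- read.csv(stays_path, comment.char = "#", stringsAsFactors = FALSE)
  assert_that(all(c("patient_id", "los", "exit_type") %in% names(stays)),
              "stays CSV must have patient_id, los, exit_type")
  assert_that(all(stays$exit_type %in% c("discharge", "death")),
              "exit_type must be 'discharge' or 'death'")
  n_days <- vapply(by_pat, length, integer(1))
  assert_that(all(stays$los == n_days[as.character(stays$patient_id)]),
              "los must equal the number of physiology days")
  if (nrow(phys)) phys <- phys[order(phys$patient_id, phys$day), ]
  rownames(phys) <- rownames(stays) <- NULL
  structure(list(physiology = if (nrow(phys)) phys else NULL,
                 stays = if (nrow(stays)) stays else NULL, config = NULL),
            class = "icu_cohort")
}

#' @rdname icu_io
#' @param config Optional configuration embedded as a provenance comment.
#' @export
write_dataset_csv <- function(data, path, config = NULL) {
  feats <- attr(data, "feature_names")
  if (is.null(feats)) feats <- sofa_feature_names()
  cols <- c("patient_id", "index_day", feats, "remaining_los", "event")
  assert_that(all(cols %in% names(data)), "dataset is missing columns")
  write_csv_with_comment(data[, cols], path, provenance_line(config))
  invisible(path)
}

#' @rdname icu_io
#' @export
read_dataset_csv <- function(path) {
  df <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  feats <- sofa_feature_names()
  expected <- c("patient_id", "index_day", feats, "remaining_los", "event")
  missing_cols <- setdiff(expected, names(df))
  assert_that(length(missing_cols) == 0,
              "dataset CSV is missing the canonical column(s): ",
              paste(missing_cols, collapse = ", "))
  extra <- setdiff(names(df), expected)
  assert_that(length(extra) == 0, "dataset CSV has unknown column(s): ",
              paste(extra, collapse = ", "))
  for (f in feats) {
    assert_that(!anyNA(df[[f]]),
                "blank predictor cell in column ", f,
                " (imputation happens at scoring time; predictors must be",
                " complete)")
  }
  df$event <- as.logical(df$event)
  df <- df[, expected]
  attr(df, "feature_names") <- feats
  df
}

stepmatrix_to_list <- function(m) lapply(seq_len(nrow(m)), function(i) m[i, ])

#' @rdname icu_io
#' @export
write_model_json <- function(model, path) {
  if (inherits(model, "icu_rsf")) {
    type <- "rsf"
  } else if (inherits(model, "icu_rf")) {
    type <- "rf"
  } else {
    icu_stop("model must be a fitted icu_rsf or icu_rf")
  }
  payload <- list(
    type = type,
    feature_names = model$feature_names,
    params = unclass(model$params),
    mtry = model$mtry,
    grid = model$grid,
    oob = model$oob,
    time = model$time,
    event = model$event,
    X = stepmatrix_to_list(model$X),
    trees = lapply(model$trees, function(tree) {
      out <- tree[c("split_var", "split_val", "left", "right")]
      if (type == "rsf") {
        out$terminal_chf <- stepmatrix_to_list(tree$terminal_chf)
      } else {
        out$terminal_value <- tree$terminal_value
      }
      out
    })
  )
  jsonlite::write_json(payload, path, digits = NA, null = "null")
  invisible(path)
}

#' @rdname icu_io
#' @export
read_model_json <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE,
                                 simplifyMatrix = TRUE)
  type <- payload$type
  assert_that(type %in% c("rsf", "rf"), "unknown model type in JSON: ", type)
  params <- payload$params
  params$max_depth <- if (is.null(params$max_depth)) Inf else params$max_depth
  trees <- lapply(seq_len(nrow_or_len(payload$trees)), function(b) {
    tr <- tree_slot(payload$trees, b)
    tr$split_var <- as.integer(tr$split_var)
    tr$left <- as.integer(tr$left)
    tr$right <- as.integer(tr$right)
    if (type == "rsf") {
      tr$terminal_chf <- as_matrix_rows(tr$terminal_chf)
    }
    tr
  })
  X <- as_matrix_rows(payload$X)
  colnames(X) <- payload$feature_names
  common <- list(trees = trees, feature_names = payload$feature_names,
                 mtry = payload$mtry, X = X, time = payload$time,
                 oob = lapply(payload$oob, as.integer))
  if (type == "rsf") {
    params <- do.call(rsf_params, params[names(formals(rsf_params))])
    structure(c(common, list(grid = payload$grid, event = payload$event,
                             params = params)),
              class = "icu_rsf")
  } else {
    params <- do.call(rf_params, params[names(formals(rf_params))])
    structure(c(common, list(params = params)), class = "icu_rf")
  }
}

nrow_or_len <- function(x) if (is.data.frame(x)) nrow(x) else length(x)

tree_slot <- function(trees, b) {
  if (is.data.frame(trees)) lapply(trees, `[[`, b) else trees[[b]]
}

as_matrix_rows <- function(x) {
  if (is.matrix(x)) return(x)
  do.call(rbind, lapply(x, as.numeric))
}
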