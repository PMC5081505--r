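#' Random Survival Forest parameters
#'
#' Hyperparameters of the survival forest. Defaults follow common random
#' survival forest practice: many trees, `mtry` near the square root of the
#' number of predictors, and splitting stopped once a daughter node would no
#' longer hold more than `min_deaths` unique event times.
#'
#' @param n_trees Number of bootstrap trees (default 1000).
#' @param mtry Number of candidate variables per split; `NULL` means
#'   `ceiling(sqrt(p))` (5 for the 19-predictor ICU dataset).
#' @param min_deaths `d0 > 0`: a split is admissible only if both daughters
#'   retain at least `d0` unique event times; large values stop growth early
#'   (a value above the number of event times leaves every tree unsplit).
#' @param max_depth Maximum tree depth, or `Inf` for unlimited.
#' @param seed Integer seed controlling bootstraps and variable sampling.
#' @param bootstrap If `FALSE`, every tree trains on the full sample (no
#'   bagging, no out-of-bag cases); used for diagnostics such as checking
#'   that an unsplit tree reproduces the cohort Nelson-Aalen estimator.
#' @return An object of class `icu_rsf_params`.
#' @export
rsf_params <- function(n_trees = 1000, mtry = NULL, min_deaths = 3,
                       max_depth = Inf, seed = 1, bootstrap = TRUE) {
  assert_that(n_trees >= 1, "n_trees must be positive")
  assert_that(min_deaths >= 1, "min_deaths must be positive")
  assert_that(is.infinite(max_depth) || max_depth >= 1,
              "max_depth must be positive or Inf")
  structure(list(n_trees = as.integer(n_trees), mtry = mtry,
                 min_deaths = as.integer(min_deaths), max_depth = max_depth,
                 seed = as.integer(seed), bootstrap = isTRUE(bootstrap)),
            class = "icu_rsf_params")
}

# Pull the predictor matrix, target and event flag out of a supervised
# dataset data frame. Any column that is not an identifier or outcome is a
# predictor, so toy datasets with fewer than 19 features work too.
dataset_parts <- function(data) {
  assert_that(is.data.frame(data), "dataset must be a data frame")
  assert_that(all(c("remaining_los", "event") %in% names(data)),
              "dataset must have remaining_los and event columns")
  feats <- attr(data, "feature_names")
  if (is.null(feats)) {
    feats <- setdiff(names(data),
                     c("patient_id", "index_day", "remaining_los", "event"))
  }
  assert_that(length(feats) >= 1, "dataset has no predictor columns")
  X <- as.matrix(data[, feats, drop = FALSE])
  storage.mode(X) <- "double"
  list(X = X, time = as.numeric(data$remaining_los),
       event = as.integer(as.logical(data$event)), features = feats)
}

#' Fit a Random Survival Forest
#'
#' Grows `n_trees` survival trees, each on a bootstrap sample of the dataset.
#' Nodes are split on the variable/cut-value pair maximising the absolute
#' standardised log-rank statistic among `mtry` randomly sampled candidate
#' variables; candidate cuts are the midpoints between consecutive distinct
#' values within the node. A split is rejected when a daughter would hold no
#' more than `min_deaths` unique event times. Terminal nodes carry the
#' Nelson-Aalen cumulative hazard of their in-bag cases, evaluated on the
#' grid of all distinct event times in the training data. Ties in the split
#' criterion resolve to the lowest variable index, then the lowest cut.
#'
#' In the ICU occupancy setting the "event" is discharge and in-ICU death is
#' right censoring, so a patient's survival function is the probability of
#' still occupying a bed.
#'
#' @param data Supervised dataset: a data frame with predictor columns plus
#'   `remaining_los` (days) and `event` (logical; `FALSE` = censored).
#' @param params An [rsf_params()] object.
#' @return An object of class `icu_rsf` with elements `trees`, `grid` (the
#'   event-time grid), `inbag`/`oob` index lists, and the training data.
#' @export
#' @examples
#' d <- data.frame(x = rep(0:1, each = 20),
#'                 remaining_los = rep(c(2, 8), each = 20) + rep(0:3, 10),
#'                 event = TRUE)
#' fit <- fit_rsf(d, rsf_params(n_trees = 10, seed = 1))
fit_rsf <- function(data, params = rsf_params()) {
  stopifnot(inherits(params, "icu_rsf_params"))
  parts <- dataset_parts(data)
  n <- nrow(parts$X)
  assert_that(n >= 1, "dataset is empty")
  grid <- sort(unique(parts$time[parts$event == 1L]))
  assert_that(length(grid) >= 1,
              "dataset holds no event (discharge) times; cannot fit")
  p <- ncol(parts$X)
  mtry <- if (is.null(params$mtry)) ceiling(sqrt(p)) else as.integer(params$mtry)
  assert_that(mtry >= 1 && mtry <= p, "mtry must lie in [1, #predictors]")
  maxd <- if (is.infinite(params$max_depth)) -1L else as.integer(params$max_depth)

  trees <- vector("list", params$n_trees)
  inbag <- vector("list", params$n_trees)
  oob <- vector("list", params$n_trees)
  with_seed(params$seed, function() {
    for (b in seq_len(params$n_trees)) {
      idx <- if (params$bootstrap) sample.int(n, n, replace = TRUE) else seq_len(n)
      trees[[b]] <<- grow_tree_cpp(parts$X, parts$time, parts$event,
                                   idx - 1L, mtry, TRUE, params$min_deaths,
                                   1L, maxd, grid)
      inbag[[b]] <<- idx
      oob[[b]] <<- setdiff(seq_len(n), idx)
    }
  })
  structure(list(trees = trees, grid = grid, feature_names = parts$features,
                 inbag = inbag, oob = oob, params = params, mtry = mtry,
                 X = parts$X, time = parts$time, event = parts$event),
            class = "icu_rsf")
}

#' @export
print.icu_rsf <- function(x, ...) {
  cat("Random Survival Forest:", length(x$trees), "trees,",
      length(x$feature_names), "predictors, mtry", x$mtry, "\n")
  cat("Training cases:", nrow(x$X), " event-time grid:",
      paste(x$grid, collapse = " "), "\n")
  invisible(x)
}

# terminal-row indices for each row of newX under one tree
tree_terminals <- function(tree, newX) {
  predict_terminal_cpp(tree$split_var, tree$split_val, tree$left, tree$right,
                       newX)
}

as_feature_matrix <- function(model, newdata) {
  if (is.matrix(newdata)) {
    X <- newdata
  } else {
    X <- as.matrix(as.data.frame(newdata)[, model$feature_names, drop = FALSE])
  }
  assert_that(ncol(X) == length(model$feature_names),
              "newdata must provide the model's ", length(model$feature_names),
              " predictors")
  storage.mode(X) <- "double"
  X
}

# n x |grid| matrix of ensemble CHF values at the event-time grid
rsf_chf_matrix <- function(model, newX) {
  acc <- matrix(0, nrow(newX), length(model$grid))
  for (tree in model$trees) {
    acc <- acc + tree$terminal_chf[tree_terminals(tree, newX), , drop = FALSE]
  }
  acc / length(model$trees)
}

#' Ensemble cumulative hazard for one patient
#'
#' Drops a predictor vector through every tree of a fitted survival forest
#' and averages the Nelson-Aalen estimators of the terminal nodes reached.
#'
#' @param model A fitted [fit_rsf()] forest.
#' @param x Numeric predictor vector (in the model's feature order) or a
#'   one-row data frame.
#' @return An [icu_stepfun()] cumulative hazard on the training event-time
#'   grid.
#' @export
ensemble_chf <- function(model, x) {
  stopifnot(inherits(model, "icu_rsf"))
  X <- if (is.numeric(x) && is.null(dim(x))) matrix(x, nrow = 1) else
    as_feature_matrix(model, x)
  chf <- rsf_chf_matrix(model, X)
  icu_stepfun(model$grid, chf[1, ])
}

#' Predict survival or cumulative hazard curves
#'
#' @param object A fitted [fit_rsf()] forest.
#' @param newdata Data frame or matrix of predictor rows.
#' @param times Evaluation times (days); defaults to the event-time grid.
#' @param type `"survival"` for S(t) = exp(-H(t)) or `"chf"` for H(t).
#' @param ... Unused.
#' @return Numeric matrix, one row per case, one column per time.
#' @export
predict.icu_rsf <- function(object, newdata, times = NULL,
                            type = c("survival", "chf"), ...) {
  type <- match.arg(type)
  X <- as_feature_matrix(object, newdata)
  chf <- rsf_chf_matrix(object, X)
  if (!is.null(times)) {
    idx <- findInterval(times, object$grid)
    chf <- cbind(0, chf)[, idx + 1L, drop = FALSE]
    colnames(chf) <- times
  } else {
    colnames(chf) <- object$grid
  }
  if (type == "survival") exp(-chf) else chf
}

# average CHF matrix over trees where each training case is out-of-bag
oob_chf_matrix <- function(model) {
  n <- nrow(model$X)
  acc <- matrix(0, n, length(model$grid))
  cnt <- numeric(n)
  for (b in seq_along(model$trees)) {
    ob <- model$oob[[b]]
    if (!length(ob)) next
    term <- tree_terminals(model$trees[[b]], model$X[ob, , drop = FALSE])
    acc[ob, ] <- acc[ob, , drop = FALSE] +
      model$trees[[b]]$terminal_chf[term, , drop = FALSE]
    cnt[ob] <- cnt[ob] + 1
  }
  if (any(cnt == 0)) {
    icu_stop(sum(cnt == 0), " training case(s) are never out-of-bag; ",
             "increase n_trees")
  }
  acc / cnt
}

# ensemble mortality: CHF summed over the event-time grid (a scalar risk
# score; larger = expected to leave sooner)
chf_mortality <- function(chf_matrix) rowSums(chf_matrix)

concordance_error <- function(time, event, mortality) {
  fit <- survival::concordance(survival::Surv(time, event) ~ mortality,
                               reverse = TRUE)
  1 - unname(fit$concordance)
}

#' Out-of-bag concordance error of a survival forest
#'
#' Computes each training case's ensemble mortality (cumulative hazard summed
#' over the event-time grid) using only trees for which the case is
#' out-of-bag, and returns 1 minus Harrell's concordance against the observed
#' (time, event) outcomes. 0 is perfect ranking, 0.5 is random.
#'
#' @param model A fitted [fit_rsf()] forest grown with bootstrapping.
#' @return Error in `[0, 1]`.
#' @export
oob_concordance_error <- function(model) {
  stopifnot(inherits(model, "icu_rsf"))
  mort <- chf_mortality(oob_chf_matrix(model))
  concordance_error(model$time, model$event, mort)
}
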