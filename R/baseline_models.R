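#' Random Forest regression parameters
#'
#' Hyperparameters of the Random Forest regression comparator that predicts
#' each patient's remaining length of stay directly. Defaults follow common
#' regression-forest practice (`mtry` about a third of the predictors,
#' terminal nodes of at least 5 cases).
#'
#' @param n_trees Number of bootstrap trees (default 1000).
#' @param mtry Candidate variables per split; `NULL` means `ceiling(p / 3)`
#'   (7 for the 19-predictor ICU dataset).
#' @param min_node_size Minimum number of cases in each daughter node.
#' @param max_depth Maximum depth, or `Inf`.
#' @param seed Integer seed.
#' @param bootstrap If `FALSE`, trees train on the full sample.
#' @return An object of class `icu_rf_params`.
#' @export
rf_params <- function(n_trees = 1000, mtry = NULL, min_node_size = 5,
                      max_depth = Inf, seed = 1, bootstrap = TRUE) {
  assert_that(n_trees >= 1, "n_trees must be positive")
  assert_that(min_node_size >= 1, "min_node_size must be positive")
  assert_that(is.infinite(max_depth) || max_depth >= 0,
              "max_depth must be non-negative or Inf")
  structure(list(n_trees = as.integer(n_trees), mtry = mtry,
                 min_node_size = as.integer(min_node_size),
                 max_depth = max_depth, seed = as.integer(seed),
                 bootstrap = isTRUE(bootstrap)),
            class = "icu_rf_params")
}

#' Fit a Random Forest regression of remaining length of stay
#'
#' Bootstrap-aggregated binary regression trees: each split minimises the
#' residual sum of squares over the candidate variables, each terminal node
#' predicts the mean target of its in-bag cases (the target itself when a
#' single case remains), and the ensemble prediction is the arithmetic mean
#' of the per-tree predictions. Censored entries contribute their observed
#' remaining stay as-is; the regression comparator has no censoring
#' mechanism.
#'
#' @param data Supervised dataset as for [fit_rsf()]; the `event` column is
#'   ignored.
#' @param params An [rf_params()] object.
#' @return An object of class `icu_rf`.
#' @export
#' @examples
#' d <- data.frame(x = 1:50, remaining_los = 1:50, event = TRUE)
#' fit <- fit_rf(d, rf_params(n_trees = 20, seed = 1))
#' predict(fit, data.frame(x = 10))
fit_rf <- function(data, params = rf_params()) {
  stopifnot(inherits(params, "icu_rf_params"))
  parts <- dataset_parts(data)
  n <- nrow(parts$X)
  assert_that(n >= 1, "dataset is empty")
  p <- ncol(parts$X)
  mtry <- if (is.null(params$mtry)) ceiling(p / 3) else as.integer(params$mtry)
  assert_that(mtry >= 1 && mtry <= p, "mtry must lie in [1, #predictors]")
  maxd <- if (is.infinite(params$max_depth)) -1L else as.integer(params$max_depth)

  trees <- vector("list", params$n_trees)
  inbag <- vector("list", params$n_trees)
  oob <- vector("list", params$n_trees)
  with_seed(params$seed, function() {
    for (b in seq_len(params$n_trees)) {
      idx <- if (params$bootstrap) sample.int(n, n, replace = TRUE) else seq_len(n)
      trees[[b]] <<- grow_tree_cpp(parts$X, parts$time, parts$event,
                                   idx - 1L, mtry, FALSE, 1L,
                                   params$min_node_size, maxd, numeric(0))
      inbag[[b]] <<- idx
      oob[[b]] <<- setdiff(seq_len(n), idx)
    }
  })
  structure(list(trees = trees, feature_names = parts$features,
                 inbag = inbag, oob = oob, params = params, mtry = mtry,
                 X = parts$X, time = parts$time),
            class = "icu_rf")
}

#' @export
print.icu_rf <- function(x, ...) {
  cat("Random Forest regression:", length(x$trees), "trees,",
      length(x$feature_names), "predictors, mtry", x$mtry, "\n")
  invisible(x)
}

# per-tree predictions for rows of newX: n x B matrix
rf_tree_predictions <- function(model, newX) {
  vapply(model$trees, function(tree) {
    tree$terminal_value[tree_terminals(tree, newX)]
  }, numeric(nrow(newX)))
}

#' Predict remaining length of stay with a regression forest
#'
#' @param object A fitted [fit_rf()] model.
#' @param newdata Data frame or matrix of predictor rows.
#' @param ... Unused.
#' @return Numeric vector of predicted remaining stays (days), the mean of
#'   the per-tree terminal values.
#' @export
predict.icu_rf <- function(object, newdata, ...) {
  X <- as_feature_matrix(object, newdata)
  preds <- rf_tree_predictions(object, X)
  if (is.null(dim(preds))) preds <- matrix(preds, nrow = nrow(X))
  rowMeans(preds)
}

#' Resampling baseline for remaining length of stay
#'
#' Predicts a patient's remaining stay by drawing uniformly at random from
#' the remaining-stay values observed in the training data. Because the
#' draws come from the data's own distribution this is a competitive
#' reference point for group-level occupancy prediction.
#'
#' @param training_targets Non-empty numeric vector of training
#'   remaining-stay values (dataset entries).
#' @param n Number of independent draws.
#' @return Numeric vector of `n` sampled remaining stays. Uses the current
#'   RNG state; seed with `set.seed()` for reproducibility.
#' @export
#' @examples
#' set.seed(1)
#' baseline_sample_los(c(2, 10), n = 5)
baseline_sample_los <- function(training_targets, n = 1) {
  assert_that(length(training_targets) > 0, "training target pool is empty")
  training_targets[sample.int(length(training_targets), n, replace = TRUE)]
}
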