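#' @useDynLib icubeds, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats plogis rnorm runif quantile median wilcox.test
#' @importFrom utils read.csv write.csv
NULL

# Classed validation error so callers (and the CLI) can distinguish bad input
# from runtime failure.
icu_stop <- function(..., class = "icu_validation_error") {
  stop(structure(
    class = c(class, "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

assert_that <- function(cond, ...) {
  if (!isTRUE(cond)) icu_stop(...)
  invisible(TRUE)
}

#' Derive a reproducible sub-seed from a master seed
#'
#' All randomness in the package flows from user-supplied integer seeds.
#' Independent stages (simulation, bootstrap, resampling, permutation) draw
#' their own sub-seed from the master seed plus a stream label, so changing
#' the consumers of one stream does not perturb the others.
#'
#' @param seed Integer master seed.
#' @param ... Further integers or strings naming the sub-stream.
#' @return A single integer in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(1, "bootstrap", 3)
derive_seed <- function(seed, ...) {
  parts <- list(...)
  h <- as.double(seed) %% 2147483629
  for (p in parts) {
    xs <- if (is.character(p)) utf8ToInt(p) else as.double(p)
    for (x in xs) h <- (h * 69069 + x + 1) %% 2147483629
  }
  as.integer(h)
}

# Evaluate f under a local RNG state seeded with `seed`; global RNG untouched.
with_seed <- function(seed, f) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  f()
}
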