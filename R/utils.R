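#' @useDynLib ctenet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats quantile sd var fft rnorm runif
NULL

# Evaluate expr under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so package functions never disturb the
# global stream.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(expr)
}

# Deterministic child seeds: a prefix-stable stream drawn from the parent seed,
# so element i does not depend on how many seeds are requested.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# Surrogate threshold: percentile with linear interpolation between order
# statistics (quantile type 7), the rule documented for the 95th-percentile test.
surrogate_threshold <- function(values, percentile = 95) {
  unname(quantile(values, percentile / 100, type = 7, names = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
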