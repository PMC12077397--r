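# Deterministic seed derivation: every stochastic stage receives its own
# child seed so any component of a large replay can be re-run in isolation.

# purpose tags for the seed tree (arbitrary but fixed small integers)
.SEED_FOLDS <- 11L
.SEED_OUTER <- 12L
.SEED_CURVE <- 21L
.SEED_PRED <- 22L
.SEED_POWER <- 23L
.SEED_DRAW <- 31L
.SEED_FIT <- 32L
.SEED_VAL <- 33L
.SEED_DISC <- 34L
.SEED_STEP <- 40L

#' Derive a child seed from a parent seed
#'
#' Folds one or more integer tags into a parent seed with a
#' Lehmer-style congruential mix, keeping the result a valid positive
#' 32-bit integer. Used throughout the package so that nested stochastic
#' stages (row draws, fold shuffles, bootstrap resamples, permutations)
#' are reproducible in isolation from a single master seed.
#'
#' @param seed integer parent seed.
#' @param ... integer tags identifying the child stream.
#' @return a positive integer seed, strictly below 2^31.
#' @export
child_seed <- function(seed, ...) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  s <- as.double(seed) %% 2147483647
  for (x in c(...)) {
    # 48271 * 2^31 < 2^47: exact in double arithmetic
    s <- (s * 48271 + as.double(x) + 1) %% 2147483647
  }
  as.integer(s + 1)
}

# run code under a temporary RNG state
with_seed <- function(seed, code) {
  withr::with_seed(seed, code)
}
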