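#' Permutation test for predictive performance
#'
#' Tests the null hypothesis of zero predictive performance by comparing
#' the observed score of paired (truth, prediction) values with its
#' distribution when the truth vector is randomly permuted against the
#' fixed predictions. P-values use the add-one convention
#' `p = (1 + #\{s_perm >= s_obs\}) / (n_perm + 1)`, so the smallest
#' attainable p is `1 / (n_perm + 1)` and p is never zero; permutation
#' scores tying the observed score count toward the null (conservative).
#' When `n! <= 5040` (n of 7 or less) all permutations are enumerated
#' instead of sampled; the same add-one convention is applied to the
#' enumerated count.
#'
#' @param truth observed target values (length `>= 3`).
#' @param prediction predictions paired with `truth`.
#' @param scorer scorer id or object.
#' @param n_perm number of Monte-Carlo permutations (default 5000, the
#'   confirmatory setting used for final external validation).
#' @param seed integer seed.
#' @param exhaustive force (`TRUE`) or forbid (`FALSE`) exhaustive
#'   enumeration; default `NULL` enumerates exactly when `n <= 7`.
#' @return the permutation p-value, in `(0, 1]`.
#' @export
permutation_test <- function(truth, prediction, scorer, n_perm = 5000,
                             seed = 1, exhaustive = NULL) {
  n <- length(truth)
  if (n < 3) stop("permutation test needs at least 3 observations")
  if (length(prediction) != n) stop("score input length mismatch")
  if (n_perm < 1) stop("n_perm must be at least 1")
  sc <- get_scorer(scorer)
  s_obs <- sc$fn(truth, prediction)
  if (is.null(exhaustive)) exhaustive <- factorial(n) <= 5040

  if (exhaustive) {
    perms <- pracma::perms(seq_len(n))
    s_perm <- apply(perms, 1, function(ix) sc$fn(truth[ix], prediction))
    (1 + sum(s_perm >= s_obs - 1e-12)) / (nrow(perms) + 1)
  } else {
    hits <- with_seed(seed, {
      sum(vapply(seq_len(n_perm), function(i) {
        sc$fn(truth[sample.int(n)], prediction) >= s_obs - 1e-12
      }, logical(1)))
    })
    (1 + hits) / (n_perm + 1)
  }
}

#' Bootstrapped power of a prospective external validation
#'
#' Estimates the probability that an external validation sample of size
#' `n_val` would yield a significant permutation test, given the
#' predictive performance observed so far. The discovery-phase
#' out-of-fold (truth, prediction) pairs are resampled with replacement
#' at size `n_val` `n_boot` times; each resample is submitted to
#' [permutation_test()] and the estimated power is the fraction of
#' resamples with `p < alpha`.
#'
#' @param sample a `prediction_sample` from [cv_predict()] (or a list
#'   with `truth`, `prediction`, `scorer_id`).
#' @param n_val candidate validation sample size (`>= 0`); sizes below 3
#'   cannot be tested and return power 0.
#' @param alpha significance level in (0, 1).
#' @param n_boot bootstrap resamples (default 100).
#' @param n_perm permutations per resample (default 500 — cheaper than
#'   the confirmatory 5000 since only the rejection fraction matters).
#' @param seed integer seed.
#' @return estimated power in `[0, 1]`.
#' @export
estimate_power <- function(sample, n_val, alpha = 0.05, n_boot = 100,
                           n_perm = 500, seed = 1) {
  if (alpha <= 0 || alpha >= 1) stop("invalid alpha")
  if (length(sample$truth) < 1) stop("empty prediction sample")
  if (n_val < 3) return(0)
  n_act <- length(sample$truth)
  rejected <- vapply(seq_len(n_boot), function(b) {
    sb <- child_seed(seed, .SEED_POWER, b)
    idx <- with_seed(sb, sample.int(n_act, n_val, replace = TRUE))
    tr <- sample$truth[idx]
    pr <- sample$prediction[idx]
    if (sample$scorer_id == "explained_variance" && stats::var(tr) == 0) {
      return(FALSE) # degenerate resample can never reject
    }
    p <- permutation_test(tr, pr, sample$scorer_id, n_perm,
                          seed = child_seed(sb, 1), exhaustive = FALSE)
    p < alpha
  }, logical(1))
  mean(rejected)
}

#' Validation power curve
#'
#' Evaluates [estimate_power()] over a grid of candidate validation
#' sizes, tracing the expected fraction of true-positive significance
#' tests as the validation sample grows.
#'
#' @inheritParams estimate_power
#' @param n_max largest validation size to evaluate.
#' @param n_grid optional integer grid; the default covers `1..n_max`,
#'   thinned to at most 20 evenly spaced points.
#' @return a `power_curve`: `n_grid`, `power`, `alpha`, `n_boot`,
#'   `n_perm`.
#' @export
compute_power_curve <- function(sample, n_max, alpha = 0.05, n_boot = 100,
                                n_perm = 500, seed = 1, n_grid = NULL) {
  if (n_max < 1) stop("n_max must be at least 1")
  if (is.null(n_grid)) {
    n_grid <- if (n_max <= 20) seq_len(n_max) else
      unique(round(seq(1, n_max, length.out = 20)))
  }
  n_grid <- sort(unique(as.integer(n_grid)))
  # seeds are tagged by the candidate n itself, so the power at a given
  # n is identical whether it is computed on a grid or in isolation
  pow <- vapply(seq_along(n_grid), function(i) {
    estimate_power(sample, n_grid[i], alpha, n_boot, n_perm,
                   seed = child_seed(seed, .SEED_POWER, n_grid[i]))
  }, numeric(1))
  structure(
    list(n_grid = n_grid, power = pow, alpha = alpha,
         n_boot = n_boot, n_perm = n_perm),
    class = "power_curve"
  )
}

#' @export
print.power_curve <- function(x, ...) {
  cat(sprintf("<power_curve> alpha=%g, n_boot=%d, n_perm=%d\n",
              x$alpha, x$n_boot, x$n_perm))
  print(data.frame(n = x$n_grid, power = x$power), row.names = FALSE)
  invisible(x)
}

#' Export a power curve as tabular text or JSON
#'
#' @param curve a `power_curve`.
#' @param path output file; `.json` extension selects JSON, else CSV.
#' @return the path, invisibly.
#' @export
write_power_curve <- function(curve, path) {
  df <- data.frame(n = curve$n_grid, power = curve$power)
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(
      list(alpha = curve$alpha, n_boot = curve$n_boot,
           n_perm = curve$n_perm, curve = df),
      path, auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}
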