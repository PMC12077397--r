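# Synthetic datasets with controlled effect size and learning-curve
# shape. Gaussian designs are used throughout because they give
# closed-form control of the population R^2 (regression) and of the
# Bayes-optimal accuracy (classification): for two unit-variance
# Gaussian classes separated by d along one direction, the optimal rule
# achieves pnorm(d / 2).

#' Generate a synthetic regression dataset
#'
#' Features are standard normal (optionally equicorrelated); the target
#' is a linear combination of all features plus Gaussian noise, scaled
#' so the population R-squared equals `target_signal`.
#'
#' @param n observations.
#' @param p features.
#' @param target_signal population R-squared in `[0, 1)`.
#' @param rho equicorrelation between features (default 0, independent;
#'   positive values give a collinear design).
#' @param seed integer seed.
#' @return an `adasplit_dataset` (regression).
#' @export
make_regression <- function(n, p = 10, target_signal = 0.5, rho = 0,
                            seed = 1) {
  if (target_signal < 0 || target_signal >= 1) stop("invalid signal level")
  if (rho < 0 || rho >= 1) stop("rho must be in [0, 1)")
  with_seed(seed, {
    X <- matrix(stats::rnorm(n * p), n, p)
    if (rho > 0) {
      # equicorrelated Gaussian: sqrt(rho) * shared factor + sqrt(1-rho) * own
      z <- stats::rnorm(n)
      X <- sqrt(rho) * z + sqrt(1 - rho) * X
    }
    beta <- stats::rnorm(p)
    # Var(X beta) under the equicorrelated design
    vf <- (1 - rho) * sum(beta^2) + rho * sum(beta)^2
    f <- drop(X %*% beta) / sqrt(vf)
    y <- sqrt(target_signal) * f + sqrt(1 - target_signal) * stats::rnorm(n)
    as_dataset(X, y, "regression")
  })
}

#' Generate a synthetic classification dataset
#'
#' Two unit-variance Gaussian classes whose means are separated by
#' `target_signal` along a direction given by `weights` (random by
#' default). The Bayes-optimal accuracy for balanced classes is
#' `pnorm(target_signal / 2)`.
#'
#' @param n observations.
#' @param p features.
#' @param target_signal class-mean separation `d >= 0` (Euclidean, equal
#'   identity covariances).
#' @param class_balance proportion of the positive class, in (0, 1);
#'   counts are rounded so a 0.5 balance differs by at most one
#'   observation.
#' @param weights optional length-p loading pattern for the separation
#'   direction (normalized internally); by default a random direction.
#' @param seed integer seed.
#' @return an `adasplit_dataset` (classification, labels 0/1).
#' @export
make_classification <- function(n, p = 10, target_signal = 2,
                                class_balance = 0.5, weights = NULL,
                                seed = 1) {
  if (target_signal < 0) stop("invalid signal level")
  if (class_balance <= 0 || class_balance >= 1) stop("invalid class balance")
  with_seed(seed, {
    u <- if (is.null(weights)) stats::rnorm(p) else as.numeric(weights)
    if (length(u) != p) stop("weights must have length p")
    u <- u / sqrt(sum(u^2))
    n1 <- max(1L, min(n - 1L, as.integer(round(n * class_balance))))
    y <- sample(c(rep(1L, n1), rep(0L, n - n1)))
    X <- matrix(stats::rnorm(n * p), n, p)
    shift <- outer(ifelse(y == 1, target_signal / 2, -target_signal / 2), u)
    as_dataset(X + shift, y, "classification")
  })
}

#' Generate a learning-curve archetype dataset
#'
#' Three canonical shapes of the dependence of predictive performance on
#' training sample size, each a classification problem with a different
#' signal structure:
#' * `flat` — weak signal in a single feature among noise: performance
#'   is low from the start and adding data barely helps.
#' * `rising` — moderate total signal spread evenly across many weak
#'   features: the model keeps improving as n grows because many small
#'   coefficients must be estimated.
#' * `plateau` — one dominant feature: performance saturates early at a
#'   high level.
#'
#' @param kind `"flat"`, `"rising"` or `"plateau"`.
#' @param n observations.
#' @param seed integer seed.
#' @return an `adasplit_dataset` (classification, balanced).
#' @export
make_archetype <- function(kind, n, seed = 1) {
  kind <- match.arg(kind, c("flat", "rising", "plateau"))
  cfg <- switch(kind,
    flat = list(p = 2, sep = 0.8, weights = c(1, 0)),
    rising = list(p = 40, sep = 3, weights = rep(1, 40)),
    plateau = list(p = 6, sep = 3, weights = c(1, rep(0, 5)))
  )
  make_classification(n, p = cfg$p, target_signal = cfg$sep,
                      class_balance = 0.5, weights = cfg$weights,
                      seed = seed)
}
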