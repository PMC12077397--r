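#' Bootstrapped learning-curve analysis
#'
#' Estimates cross-validated predictive performance as a function of
#' training sample size. For each size m in the grid, `n_boot` subsamples
#' of size m are drawn without replacement from the acquired data
#' (stratified for classification, preserving the class ratio to within
#' one observation), each is scored by nested cross-validation
#' ([cv_predict()] + [score()]), and the per-size mean and 2.5/97.5
#' percentile bootstrap interval are recorded.
#'
#' @param dataset acquired data (an `adasplit_dataset`).
#' @param spec a [model_spec()]; defaults to the task's standard spec.
#' @param grid ascending integer sample sizes, each `<= n`; the default
#'   places up to five evenly spaced points between
#'   `max(12, smallest size feasible for cross-validation)` and n.
#' @param n_boot bootstrap subsamples per grid size (default 50).
#' @param seed integer seed.
#' @return a `learning_curve`: `sizes`, `scores` (per-size mean),
#'   `ci_low`, `ci_high`, `boot_scores` (n_boot x sizes matrix),
#'   `n_boot`, `scorer_id`, `n_act`.
#' @export
bootstrap_learning_curve <- function(dataset, spec = NULL, grid = NULL,
                                     n_boot = 50, seed = 1) {
  stopifnot(inherits(dataset, "adasplit_dataset"))
  if (is.null(spec)) spec <- default_spec(dataset)
  if (is.null(grid)) grid <- default_size_grid(dataset, spec)
  grid <- sort(unique(as.integer(grid)))
  if (max(grid) > dataset$n) stop("grid exceeds acquired sample")
  check_cv_feasible(dataset, spec, min(grid))

  boot <- matrix(NA_real_, n_boot, length(grid))
  for (i in seq_along(grid)) {
    m <- grid[i]
    for (b in seq_len(n_boot)) {
      s_ib <- child_seed(seed, .SEED_CURVE, i, b)
      idx <- subsample_idx(dataset, m, s_ib)
      ps <- cv_predict(ds_slice(dataset, idx), spec, s_ib)
      boot[b, i] <- score(ps$truth, ps$prediction, spec$scorer_id)
    }
  }
  ci <- apply(boot, 2, stats::quantile, probs = c(0.025, 0.975), names = FALSE)
  structure(
    list(sizes = grid, scores = colMeans(boot),
         ci_low = ci[1, ], ci_high = ci[2, ],
         boot_scores = boot, n_boot = n_boot,
         scorer_id = spec$scorer_id, n_act = dataset$n),
    class = "learning_curve"
  )
}

# default grid: <=5 evenly spaced points from max(12, feasible) to n
default_size_grid <- function(dataset, spec, n_points = 5) {
  lo <- max(12, min_cv_size(dataset, spec))
  n <- dataset$n
  if (n <= lo) return(n)
  unique(round(seq(lo, n, length.out = n_points)))
}

# smallest subsample size for which stratified CV with >=2 folds works
min_cv_size <- function(dataset, spec) {
  if (dataset$task == "regression") return(4L)
  prop <- min(mean(dataset$target), 1 - mean(dataset$target))
  m <- ceiling(3 / prop) # stratified subsample keeps >=3 minority members
  max(6L, as.integer(m))
}

check_cv_feasible <- function(dataset, spec, m) {
  idx <- subsample_idx(dataset, m, 1L)
  make_folds(dataset$target[idx], dataset$task, spec$cv_folds, 1L)
  invisible(TRUE)
}

# subsample without replacement; stratified for classification so the
# class ratio is preserved to +/- 1 observation
subsample_idx <- function(dataset, m, seed) {
  n <- dataset$n
  if (m > n) stop("grid exceeds acquired sample")
  with_seed(seed, {
    if (dataset$task == "classification") {
      i1 <- which(dataset$target == 1)
      i0 <- which(dataset$target == 0)
      m1 <- round(m * length(i1) / n)
      m1 <- max(1L, min(m - 1L, as.integer(m1)))
      sample(c(sample(i1, m1), sample(i0, m - m1)))
    } else {
      sample.int(n, m)
    }
  })
}

#' Last point of a learning curve
#'
#' Returns the bootstrapped performance estimate at the largest grid
#' size, i.e. the current predictive performance `s_act` on the full
#' acquired sample.
#'
#' @param curve a `learning_curve`.
#' @return a single numeric score.
#' @export
actual_score <- function(curve) {
  stopifnot(inherits(curve, "learning_curve"), length(curve$scores) >= 1)
  curve$scores[[length(curve$scores)]]
}

#' Tangent extrapolation of full-budget performance
#'
#' Extends the learning curve linearly from its last segment, assuming
#' the latest growth rate persists for the remaining observations. For
#' concave (saturating) learning curves this is an optimistic estimate —
#' an upper bound on the performance attainable at `n_total` — which is
#' exactly what makes it useful for detecting a plateau: when even the
#' optimistic bound promises no relevant gain, further discovery data
#' cannot help. A negative last-segment slope is retained, so a
#' declining curve extrapolates below the current score. The result is
#' clipped to the scorer's attainable upper bound.
#'
#' @param curve a `learning_curve` with at least two grid points.
#' @param n_total total sample-size budget (`>=` the last grid size).
#' @return estimated score after training on `n_total` observations.
#' @export
extrapolate_tangent <- function(curve, n_total) {
  stopifnot(inherits(curve, "learning_curve"))
  k <- length(curve$sizes)
  if (k < 2) stop("cannot extrapolate")
  if (n_total < curve$sizes[k]) stop("n_total below last grid size")
  slope <- (curve$scores[k] - curve$scores[k - 1]) /
    (curve$sizes[k] - curve$sizes[k - 1])
  s_hat <- curve$scores[k] + slope * (n_total - curve$sizes[k])
  min(s_hat, get_scorer(curve$scorer_id)$upper)
}

#' @export
print.learning_curve <- function(x, ...) {
  cat(sprintf("<learning_curve> %s, n_boot=%d\n", x$scorer_id, x$n_boot))
  print(as.data.frame(x), row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.learning_curve <- function(x, ...) {
  data.frame(size = x$sizes, score = x$scores,
             ci_low = x$ci_low, ci_high = x$ci_high)
}

#' Export a learning curve as tabular text or JSON
#'
#' @param curve a `learning_curve`.
#' @param path output file; `.json` extension selects JSON, anything
#'   else CSV.
#' @return the path, invisibly.
#' @export
write_learning_curve <- function(curve, path) {
  df <- as.data.frame(curve)
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(
      list(scorer = curve$scorer_id, n_boot = curve$n_boot, curve = df),
      path, auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}
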