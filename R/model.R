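#' Specify the reference model
#'
#' The stopping rule is evaluated against one of two reference
#' estimators: ridge regression (regression tasks) or L2-regularized
#' logistic regression (classification tasks). The strength of the L2
#' penalty is tuned internally by k-fold cross-validation over a small
#' grid.
#'
#' @param task `"classification"` or `"regression"`.
#' @param regularization_grid positive penalty values to tune over;
#'   default `c(0.1, 1, 10)`. Values are on the scale of the classical
#'   ridge objective `loss + penalty * ||beta||^2`.
#' @param cv_folds target number of folds k (default 5). The effective k
#'   is reduced automatically when the sample is too small: for
#'   classification k never exceeds the minority class count (so every
#'   stratified fold contains both classes), for regression it never
#'   exceeds `floor(n/2)`.
#' @param scorer_id scorer used for tuning and reporting; defaults to
#'   accuracy (classification) or neg. mean absolute error (regression).
#' @return a `model_spec` list.
#' @export
model_spec <- function(task,
                       regularization_grid = c(0.1, 1, 10),
                       cv_folds = 5,
                       scorer_id = NULL) {
  task <- match.arg(task, c("classification", "regression"))
  if (length(regularization_grid) < 1 || any(regularization_grid <= 0)) {
    stop("regularization grid must be non-empty and positive")
  }
  if (cv_folds < 2) stop("cv_folds must be at least 2")
  if (is.null(scorer_id)) scorer_id <- default_scorer_id(task)
  sc <- get_scorer(scorer_id)
  if (sc$task != task) {
    stop(sprintf("scorer '%s' is incompatible with task '%s'", scorer_id, task))
  }
  structure(
    list(task = task,
         regularization_grid = sort(unique(as.numeric(regularization_grid))),
         cv_folds = as.integer(cv_folds), scorer_id = scorer_id),
    class = "model_spec"
  )
}

# spec matching a dataset's task with all defaults
default_spec <- function(dataset) model_spec(dataset$task)

#' Build cross-validation fold assignments
#'
#' Classification folds are stratified: within each class, indices are
#' shuffled and dealt round-robin, so every fold contains at least one
#' member of each class. Regression folds are contiguous blocks of a
#' seeded shuffle.
#'
#' @param target the target vector (0/1 for classification).
#' @param task task kind.
#' @param k requested number of folds; reduced to the largest feasible
#'   value (see [model_spec()]).
#' @param seed integer seed for the shuffle.
#' @return integer vector of fold ids in `1..k_eff`.
#' @export
make_folds <- function(target, task, k, seed) {
  n <- length(target)
  if (task == "classification") {
    counts <- table(target)
    if (length(counts) < 2) stop("degenerate target")
    cmin <- min(counts)
    k_eff <- min(k, cmin)
    # every training partition must keep >= 2 members of each class
    if (k_eff >= 2 && cmin - ceiling(cmin / k_eff) < 2) k_eff <- cmin
    if (k_eff < 2 || cmin - ceiling(cmin / k_eff) < 2) {
      stop("insufficient sample for cross-validation")
    }
  } else {
    k_eff <- min(k, floor(n / 2))
    if (k_eff < 2) stop("insufficient sample for cross-validation")
  }
  folds <- integer(n)
  with_seed(seed, {
    if (task == "classification") {
      for (cl in unique(target)) {
        idx <- sample(which(target == cl))
        folds[idx] <- rep_len(seq_len(k_eff), length(idx))
      }
    } else {
      idx <- sample.int(n)
      folds[idx] <- as.integer(cut(seq_len(n), breaks = k_eff, labels = FALSE))
    }
  })
  folds
}

# center/scale constants learned from a training partition only
fit_preprocessing <- function(X) {
  center <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[!is.finite(scl) | scl == 0] <- 1
  list(center = center, scale = scl)
}

apply_preprocessing <- function(X, prep) {
  sweep(sweep(X, 2, prep$center, "-"), 2, prep$scale, "/")
}

# Fit the full ridge/logistic path over the penalty grid on (already
# standardized) training data; returns coefficients per grid value.
# glmnet parametrizes the ridge penalty per-observation, hence the /n.
fit_penalized_path <- function(Xs, y, task, grid) {
  n <- nrow(Xs)
  pad <- ncol(Xs) == 1 # glmnet needs >= 2 columns; a zero column is inert
  if (pad) Xs <- cbind(Xs, pad___ = 0)
  lam <- sort(grid, decreasing = TRUE) / n
  fam <- if (task == "classification") "binomial" else "gaussian"
  # small-class warnings are routine when the learning curve subsamples
  # down to its smallest grid sizes
  fit <- suppressWarnings(
    glmnet::glmnet(Xs, y, family = fam, alpha = 0, lambda = lam,
                   standardize = FALSE, thresh = 1e-9))
  cf <- as.matrix(stats::coef(fit)) # (p+1[+pad]) x length(grid)
  colnames(cf) <- as.character(sort(grid, decreasing = TRUE))
  if (pad) cf <- cf[-nrow(cf), , drop = FALSE]
  cf
}

linear_predict <- function(intercept, beta, Xs) {
  drop(Xs %*% beta) + intercept
}

#' Fit a tuned reference model
#'
#' Tunes the L2 penalty by k-fold cross-validation over
#' `spec$regularization_grid` (preprocessing constants are re-learned
#' inside every training fold, so no information leaks from held-out
#' folds), then refits on the full input with the selected penalty. On
#' ties in mean CV score the largest (most strongly regularized) grid
#' value wins.
#'
#' @param dataset an `adasplit_dataset`.
#' @param spec a [model_spec()]; defaults to the task's standard spec.
#' @param seed integer seed controlling the fold shuffle.
#' @return an `adasplit_model` with fields `coefficients`, `intercept`,
#'   `chosen_regularization`, `preprocessing` (training center/scale),
#'   `task`, `n_train`, `cv_score` (mean CV score of the chosen penalty)
#'   and `cv_scores` (per grid value).
#' @export
fit_tuned <- function(dataset, spec = NULL, seed = 1) {
  stopifnot(inherits(dataset, "adasplit_dataset"))
  if (is.null(spec)) spec <- default_spec(dataset)
  if (spec$task != dataset$task) stop("spec task does not match dataset task")
  if (dataset$task == "classification" && length(unique(dataset$target)) < 2) {
    stop("degenerate target")
  }
  scorer <- get_scorer(spec$scorer_id)
  grid <- spec$regularization_grid
  folds <- tryCatch(
    make_folds(dataset$target, dataset$task, spec$cv_folds,
               child_seed(seed, .SEED_FOLDS)),
    error = function(e) NULL)
  if (is.null(folds)) {
    # too small to tune: fall back to the most regularized grid value
    # (the same preference as the tie-break) fitted on the full input
    return(refit_full(dataset, spec, chosen = max(grid),
                      cv_scores = stats::setNames(
                        rep(NA_real_, length(grid)), as.character(grid)),
                      folds = NULL))
  }
  k <- max(folds)

  fold_scores <- matrix(NA_real_, k, length(grid),
                        dimnames = list(NULL, as.character(grid)))
  for (j in seq_len(k)) {
    tr <- folds != j
    prep <- fit_preprocessing(dataset$features[tr, , drop = FALSE])
    Xs_tr <- apply_preprocessing(dataset$features[tr, , drop = FALSE], prep)
    Xs_te <- apply_preprocessing(dataset$features[!tr, , drop = FALSE], prep)
    cf <- fit_penalized_path(Xs_tr, dataset$target[tr], dataset$task, grid)
    for (g in as.character(grid)) {
      lp <- linear_predict(cf[1, g], cf[-1, g], Xs_te)
      pred <- if (dataset$task == "classification") as.integer(lp > 0) else lp
      fold_scores[j, g] <- scorer$fn(dataset$target[!tr], pred)
    }
  }
  cv_scores <- colMeans(fold_scores)
  # ties broken toward the largest penalty (grid is sorted ascending)
  best <- max(which(cv_scores >= max(cv_scores) - 1e-12))
  refit_full(dataset, spec, chosen = grid[best], cv_scores = cv_scores,
             folds = folds)
}

refit_full <- function(dataset, spec, chosen, cv_scores, folds) {
  prep <- fit_preprocessing(dataset$features)
  Xs <- apply_preprocessing(dataset$features, prep)
  cf <- fit_penalized_path(Xs, dataset$target, dataset$task,
                           spec$regularization_grid)
  g <- as.character(chosen)
  structure(
    list(coefficients = stats::setNames(cf[-1, g], colnames(dataset$features)),
         intercept = unname(cf[1, g]),
         chosen_regularization = chosen,
         preprocessing = prep,
         task = dataset$task,
         labels = dataset$labels,
         scorer_id = spec$scorer_id,
         n_train = dataset$n,
         cv_score = unname(cv_scores[g]),
         cv_scores = cv_scores,
         folds = folds),
    class = "adasplit_model"
  )
}

#' Predict from a fitted reference model
#'
#' Applies the stored training preprocessing, then the linear predictor.
#' Classification returns hard 0/1 labels from the sign of the linear
#' score (threshold 0, i.e. probability 0.5).
#'
#' @param object an `adasplit_model`.
#' @param newdata numeric feature matrix with the model's p columns.
#' @param ... unused.
#' @return numeric predictions (regression) or integer 0/1 labels.
#' @export
predict.adasplit_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$coefficients)) stop("feature mismatch")
  Xs <- apply_preprocessing(newdata, object$preprocessing)
  lp <- linear_predict(object$intercept, object$coefficients, Xs)
  if (object$task == "classification") as.integer(lp > 0) else lp
}

#' @export
print.adasplit_model <- function(x, ...) {
  cat(sprintf(
    "<adasplit_model> %s, p=%d, n_train=%d, penalty=%g, cv %s=%.4f\n",
    if (x$task == "classification") "L2 logistic" else "ridge",
    length(x$coefficients), x$n_train, x$chosen_regularization,
    x$scorer_id, x$cv_score))
  invisible(x)
}

#' Nested cross-validated out-of-fold predictions
#'
#' Every observation is predicted by a model that never saw it: the data
#' are split into outer folds, and within each outer training set the
#' penalty is tuned by an inner cross-validation ([fit_tuned()]), giving
#' a nested CV estimate of out-of-sample performance.
#'
#' @inheritParams fit_tuned
#' @return a `prediction_sample`: list with `truth` and `prediction`
#'   vectors of length n (pairs aligned by observation), `scorer_id`,
#'   `task`, `folds` (outer fold ids) and `fold_details` (per outer fold:
#'   preprocessing constants and chosen penalty, for leakage audits).
#' @export
cv_predict <- function(dataset, spec = NULL, seed = 1) {
  stopifnot(inherits(dataset, "adasplit_dataset"))
  if (is.null(spec)) spec <- default_spec(dataset)
  folds <- make_folds(dataset$target, dataset$task, spec$cv_folds,
                      child_seed(seed, .SEED_OUTER))
  pred <- rep(NA_real_, dataset$n)
  details <- vector("list", max(folds))
  for (j in seq_len(max(folds))) {
    tr <- which(folds != j)
    te <- which(folds == j)
    m <- fit_tuned(ds_slice(dataset, tr), spec, child_seed(seed, .SEED_OUTER, j))
    pred[te] <- predict(m, dataset$features[te, , drop = FALSE])
    details[[j]] <- list(preprocessing = m$preprocessing,
                         chosen_regularization = m$chosen_regularization)
  }
  structure(
    list(truth = dataset$target, prediction = pred,
         scorer_id = spec$scorer_id, task = dataset$task,
         folds = folds, fold_details = details),
    class = "prediction_sample"
  )
}
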