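# Scorers are uniformly higher-is-better so the stopping rule can compare
# and extrapolate them without per-metric case handling.

#' Look up a performance scorer
#'
#' Three scorers are provided, all oriented so that larger is better:
#' * `accuracy` — fraction of exact label matches, in \[0, 1\]
#'   (classification).
#' * `neg_mean_absolute_error` — minus the mean absolute error, upper
#'   bound 0 (regression).
#' * `explained_variance` — `1 - Var(truth - pred) / Var(truth)`, upper
#'   bound 1 (regression).
#'
#' @param id scorer id string, or an object previously returned by
#'   `get_scorer()` (passed through).
#' @return a list with fields `id`, `task`, `upper` (attainable upper
#'   bound, used to clip tangent extrapolation), `fn(truth, pred)` and
#'   `chance(truth)` — the reference value expected under no association
#'   (majority-class rate for accuracy; the score of the best constant
#'   prediction for the regression scorers).
#' @export
get_scorer <- function(id) {
  if (is.list(id) && !is.null(id$fn)) return(id)
  switch(
    id,
    accuracy = list(
      id = "accuracy", task = "classification", upper = 1,
      fn = function(truth, pred) mean(truth == pred),
      chance = function(truth) max(table(truth)) / length(truth)
    ),
    neg_mean_absolute_error = list(
      id = "neg_mean_absolute_error", task = "regression", upper = 0,
      fn = function(truth, pred) -mean(abs(truth - pred)),
      chance = function(truth) -mean(abs(truth - stats::median(truth)))
    ),
    explained_variance = list(
      id = "explained_variance", task = "regression", upper = 1,
      fn = function(truth, pred) {
        vt <- stats::var(truth)
        if (vt == 0) stop("zero-variance target")
        1 - stats::var(truth - pred) / vt
      },
      chance = function(truth) 0
    ),
    stop("unknown scorer: ", id)
  )
}

#' Score predictions against the truth
#'
#' @param truth observed target values.
#' @param predictions predicted values, same length as `truth`.
#' @param scorer scorer id or object (see [get_scorer()]).
#' @return a single numeric score, higher is better.
#' @export
score <- function(truth, predictions, scorer) {
  if (length(truth) == 0) stop("empty score input")
  if (length(truth) != length(predictions)) stop("score input length mismatch")
  sc <- get_scorer(scorer)
  sc$fn(truth, predictions)
}

# default scorer per task (accuracy / neg MAE, mirroring the reference
# models used for classification and regression respectively)
default_scorer_id <- function(task) {
  if (task == "classification") "accuracy" else "neg_mean_absolute_error"
}
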