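#' Construct a dataset for adaptive splitting
#'
#' A dataset bundles a numeric feature matrix with a prediction target and
#' a task kind. Classification targets are stored as 0/1 integers together
#' with the original two labels; regression targets are numeric.
#'
#' @param features numeric matrix, n observations x p features. Column
#'   names are kept (generated as `f1..fp` when absent).
#' @param target vector of length n: numeric for regression, any
#'   two-valued vector for classification.
#' @param task `"classification"`, `"regression"`, or `NULL` to detect:
#'   a target with exactly two distinct values is treated as
#'   classification, anything else as regression.
#' @return an object of class `adasplit_dataset` with fields `features`,
#'   `target` (0/1 integer for classification), `task`, `labels`
#'   (classification only: the original labels for 0 and 1) and `n`, `p`.
#' @export
as_dataset <- function(features, target, task = NULL) {
  features <- as.matrix(features)
  if (!is.numeric(features)) stop("features must be numeric")
  n <- nrow(features)
  p <- ncol(features)
  if (n < 1 || p < 1) stop("dataset must have at least one row and one feature")
  if (length(target) != n) stop("target length must match number of rows")
  if (anyNA(features) || anyNA(target)) stop("missing data not supported")
  if (is.null(colnames(features))) colnames(features) <- paste0("f", seq_len(p))

  uniq <- unique(target)
  if (is.null(task)) {
    task <- if (length(uniq) == 2) "classification" else "regression"
  }
  task <- match.arg(task, c("classification", "regression"))

  labels <- NULL
  if (task == "classification") {
    if (length(uniq) != 2) {
      stop(if (length(uniq) < 2) "degenerate target" else
        "classification target must have exactly 2 distinct labels")
    }
    labels <- sort(as.character(uniq))
    target <- as.integer(as.character(target) == labels[2])
  } else {
    if (!is.numeric(target)) stop("regression target must be numeric")
    target <- as.numeric(target)
  }

  structure(
    list(features = features, target = target, task = task,
         labels = labels, n = n, p = p),
    class = "adasplit_dataset"
  )
}

#' Take a row subset of a dataset
#'
#' @param dataset an `adasplit_dataset`.
#' @param idx integer row indices.
#' @return an `adasplit_dataset` with the selected rows, preserving task
#'   and label coding (no re-detection).
#' @export
ds_slice <- function(dataset, idx) {
  stopifnot(inherits(dataset, "adasplit_dataset"))
  out <- dataset
  out$features <- dataset$features[idx, , drop = FALSE]
  out$target <- dataset$target[idx]
  out$n <- length(idx)
  out
}

#' @export
print.adasplit_dataset <- function(x, ...) {
  cat(sprintf("<adasplit_dataset> %d obs x %d features, task: %s\n",
              x$n, x$p, x$task))
  if (x$task == "classification") {
    tab <- table(factor(x$target, levels = 0:1))
    cat(sprintf("  classes: %s=%d, %s=%d\n",
                x$labels[1], tab[[1]], x$labels[2], tab[[2]]))
  }
  invisible(x)
}
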