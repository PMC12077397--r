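#' Read a dataset from a delimited text file
#'
#' Expects a header row, numeric feature columns and a named target
#' column. A target with exactly two distinct values is treated as a
#' classification label (any coding: 0/1, strings, ...), anything else
#' as a regression target; pass `task` to override.
#'
#' @param path file path.
#' @param target_column name of the target column (default `"target"`).
#' @param delimiter field delimiter (default `","`; use `"\t"` for TSV).
#' @param task optional task override.
#' @return an `adasplit_dataset`.
#' @export
read_dataset <- function(path, target_column = "target", delimiter = ",",
                         task = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- data.table::fread(path, sep = delimiter, header = TRUE,
                          data.table = FALSE, na.strings = c("NA", ""))
  if (!target_column %in% names(dt)) stop("target not found")
  if (anyNA(dt)) stop("missing data not supported")
  target <- dt[[target_column]]
  feats <- dt[, setdiff(names(dt), target_column), drop = FALSE]
  if (!all(vapply(feats, is.numeric, logical(1)))) {
    stop("all feature columns must be numeric")
  }
  as_dataset(as.matrix(feats), target, task)
}

#' Write a dataset to CSV
#'
#' Inverse of [read_dataset()]: features plus a target column (original
#' labels restored for classification).
#'
#' @param dataset an `adasplit_dataset`.
#' @param path output path.
#' @param target_column target column name (default `"target"`).
#' @return the path, invisibly.
#' @export
write_dataset <- function(dataset, path, target_column = "target") {
  stopifnot(inherits(dataset, "adasplit_dataset"))
  df <- as.data.frame(dataset$features)
  tgt <- dataset$target
  if (dataset$task == "classification") tgt <- dataset$labels[tgt + 1]
  df[[target_column]] <- tgt
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
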