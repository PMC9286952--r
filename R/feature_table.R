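#' Construct a feature table
#'
#' A feature table couples an `n x p` numeric feature matrix with a binary
#' label vector. Feature kinds (discrete vs continuous) control whether a
#' column is discretized before mutual-information estimation; by default a
#' column with at most `discrete_max_levels` unique values is treated as
#' discrete.
#'
#' @param values numeric matrix or data.frame of features (no missing
#'   values).
#' @param labels binary vector (0/1, logical, or two-level factor).
#' @param feature_names optional column names (taken from `values` if
#'   present).
#' @param kinds optional character vector of `"discrete"`/`"continuous"`
#'   per feature.
#' @param discrete_max_levels unique-value threshold for the automatic
#'   kind detection (default 10).
#' @return an object of class `feature_table`.
#' @export
feature_table <- function(values, labels, feature_names = NULL,
                          kinds = NULL, discrete_max_levels = 10L) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (anyNA(values)) stop("feature values contain missing entries")
  if (is.factor(labels)) labels <- as.integer(labels) - 1L
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) stop("labels must be binary (0/1)")
  if (length(labels) != nrow(values)) stop("labels/values length mismatch")
  if (nrow(values) < 2L) stop("need at least 2 samples")
  if (is.null(feature_names)) {
    feature_names <- colnames(values)
    if (is.null(feature_names)) {
      feature_names <- paste0("x", seq_len(ncol(values)))
    }
  }
  colnames(values) <- feature_names
  if (is.null(kinds)) {
    kinds <- vapply(seq_len(ncol(values)), function(j) {
      if (length(unique(values[, j])) <= discrete_max_levels) "discrete"
      else "continuous"
    }, character(1))
  }
  stopifnot(length(kinds) == ncol(values),
            all(kinds %in% c("discrete", "continuous")))
  structure(list(values = values, labels = labels,
                 feature_names = feature_names, kinds = kinds),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d samples x %d features (%d positive labels)\n",
              nrow(x$values), ncol(x$values), sum(x$labels)))
  invisible(x)
}

#' @export
as.data.frame.feature_table <- function(x, ..., label_column = "label") {
  df <- as.data.frame(x$values)
  df[[label_column]] <- x$labels
  df
}

#' Read a feature table from CSV
#'
#' Expects an RFC-4180 CSV with a header row; one column holds the binary
#' label, all others are numeric features.
#'
#' @param path CSV file path.
#' @param label name of the label column.
#' @param ... passed to [feature_table()].
#' @return a `feature_table`.
#' @export
read_feature_table <- function(path, label, ...) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!label %in% names(df)) {
    stop(sprintf("label column '%s' not found in %s", label, path))
  }
  y <- df[[label]]
  df[[label]] <- NULL
  feature_table(as.matrix(df), y, ...)
}

#' Write a feature table to CSV
#'
#' @param x a `feature_table`.
#' @param path output CSV path.
#' @param label_column name used for the label column.
#' @export
write_feature_table <- function(x, path, label_column = "label") {
  utils::write.csv(as.data.frame(x, label_column = label_column), path,
                   row.names = FALSE)
  invisible(path)
}

#' Restrict a feature table to a subset of features
#'
#' @param x a `feature_table`.
#' @param features character or integer vector of features to keep.
#' @return a new `feature_table`.
#' @export
subset_features <- function(x, features) {
  if (is.character(features)) {
    features <- match(features, x$feature_names)
    if (anyNA(features)) stop("unknown feature name(s)")
  }
  feature_table(x$values[, features, drop = FALSE], x$labels,
                kinds = x$kinds[features])
}
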