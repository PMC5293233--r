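# Training-set container and ARFF/CSV serialization.

#' Construct a training dataset
#'
#' @param x numeric matrix, reports in rows, named feature columns.
#' @param y factor of class labels (levels = full class set).
#' @param report_ids character vector of report identifiers.
#' @param scheme feature-selection scheme that produced the columns.
#' @param k subset size used (integer or \code{"all"}).
#' @return object of class \code{training_dataset}.
#' @export
training_dataset <- function(x, y, report_ids = NULL, scheme = "unknown",
                             k = "all") {
  x <- as.matrix(x)
  y <- as.factor(y)
  stopifnot(nrow(x) == length(y), !is.null(colnames(x)))
  if (is.null(report_ids)) report_ids <- as.character(seq_len(nrow(x)))
  structure(list(x = x, y = y, report_ids = as.character(report_ids),
                 scheme = scheme, k = k),
            class = "training_dataset")
}

#' @export
print.training_dataset <- function(x, ...) {
  cat("<training_dataset>", nrow(x$x), "reports x", ncol(x$x),
      "features | scheme:", x$scheme, " k:", as.character(x$k),
      "| classes:", nlevels(x$y), "\n")
  invisible(x)
}

#' @export
dim.training_dataset <- function(x) dim(x$x)

#' Write a training dataset to ARFF
#'
#' Numeric attributes keep their feature names; the nominal class attribute
#' is written last and declared with the full class level set, so the file
#' round-trips through any standard ARFF reader.
#'
#' @param dataset a \code{\link{training_dataset}}.
#' @param path output \code{.arff} path.
#' @return \code{path}, invisibly.
#' @export
write_dataset_arff <- function(dataset, path) {
  df <- as.data.frame(dataset$x)
  df$class <- dataset$y
  foreign::write.arff(df, path, relation = paste0("mortcod_", dataset$scheme))
  invisible(path)
}

#' Read a training dataset back from ARFF
#'
#' @param path \code{.arff} path (class attribute last, as written by
#'   \code{\link{write_dataset_arff}}).
#' @param scheme,k provenance to record on the result.
#' @return a \code{\link{training_dataset}}.
#' @export
read_dataset_arff <- function(path, scheme = "unknown", k = "all") {
  df <- foreign::read.arff(path)
  y <- df[[ncol(df)]]
  x <- as.matrix(df[, -ncol(df), drop = FALSE])
  training_dataset(x, y, scheme = scheme, k = k)
}

#' Write the CSV mirror of a training dataset
#'
#' @inheritParams write_dataset_arff
#' @param path output \code{.csv} path.
#' @return \code{path}, invisibly.
#' @export
write_dataset_csv <- function(dataset, path) {
  df <- data.frame(report_id = dataset$report_ids,
                   as.data.frame(dataset$x), check.names = FALSE)
  df$class <- dataset$y
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
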