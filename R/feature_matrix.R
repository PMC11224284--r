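#' Samples-by-features matrix with phenotype labels
#'
#' The common container handed between the feature builders, the classifier
#' bank and the selection routines: a numeric matrix with sample IDs as row
#' names, feature names as column names, and a `labels` attribute holding one
#' phenotype (`"case"`/`"control"`/`"unknown"`) per sample.
#'
#' @param values numeric matrix (samples x features) with dimnames.
#' @param labels character vector of phenotypes, one per row of `values`.
#' @return an object of class `tcr_features`.
#' @export
feature_matrix <- function(values, labels = NULL) {
  stopifnot(is.matrix(values))
  if (is.null(rownames(values)) && nrow(values) > 0)
    stop("values must have sample_id rownames", call. = FALSE)
  if (is.null(colnames(values)) && ncol(values) > 0)
    stop("values must have feature-name colnames", call. = FALSE)
  if (anyDuplicated(colnames(values)))
    stop("duplicate feature names", call. = FALSE)
  if (is.null(labels)) labels <- rep("unknown", nrow(values))
  stopifnot(length(labels) == nrow(values))
  structure(values, labels = as.character(labels), class = "tcr_features")
}

#' @export
print.tcr_features <- function(x, ...) {
  cat(sprintf("<tcr_features> %d samples x %d features (%s)\n",
              nrow(x), ncol(x),
              paste(sprintf("%s=%d", names(table(attr(x, "labels")))
                            , as.integer(table(attr(x, "labels")))),
                    collapse = ", ")))
  invisible(x)
}

#' @rdname feature_matrix
#' @param fm a `tcr_features` object.
#' @export
feature_labels <- function(fm) attr(fm, "labels")

# subset columns, keeping class + labels
fm_select <- function(fm, features) {
  missing <- setdiff(features, colnames(fm))
  if (length(missing))
    stop("features not in matrix: ", paste(missing, collapse = ", "),
         call. = FALSE)
  feature_matrix(unclass(fm)[, features, drop = FALSE], feature_labels(fm))
}

#' Write / read a feature matrix as TSV
#'
#' The on-disk form has a `sample_id` first column, one column per feature,
#' and (when labels are informative) a final `phenotype` column. The
#' round-trip `read_matrix(write_matrix(m))` reproduces values, names and
#' labels exactly; 0/1 presence matrices are written with integer tokens.
#'
#' @param fm a `tcr_features` object.
#' @param path output TSV path.
#' @return `write_matrix` returns `path` invisibly; `read_matrix` returns a
#'   `tcr_features`.
#' @export
write_matrix <- function(fm, path) {
  vals <- unclass(fm)
  attr(vals, "labels") <- NULL
  df <- data.frame(sample_id = rownames(fm), check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (ncol(fm) > 0) {
    store <- as.data.frame(vals, check.names = FALSE)
    if (all(vals == as.integer(vals))) {
      store[] <- lapply(store, as.integer)
    }
    df <- cbind(df, store)
  }
  labels <- feature_labels(fm)
  if (any(labels != "unknown")) df$phenotype <- labels
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  stopifnot("sample_id" %in% names(df))
  labels <- if ("phenotype" %in% names(df)) df$phenotype else NULL
  feats <- setdiff(names(df), c("sample_id", "phenotype"))
  vals <- as.matrix(df[, feats, drop = FALSE])
  if (is.character(vals)) {  # 0-feature edge case read as character
    vals <- matrix(numeric(0), nrow = nrow(df), ncol = 0)
  }
  storage.mode(vals) <- "double"
  rownames(vals) <- as.character(df$sample_id)
  colnames(vals) <- feats
  feature_matrix(vals, labels)
}
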