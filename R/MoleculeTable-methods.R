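#' @include AllClasses.R
NULL

#' Construct a MoleculeTable
#'
#' Low-level constructor; most users arrive at a table through
#' [loadTable()], [maccsFeaturize()] or [generateSynthetic()].
#'
#' @param features numeric matrix with unique column names.
#' @param labels numeric label vector.
#' @param taskKind `"classification"`, `"regression"`, or `NULL` to infer
#'   from the labels (values within \{0, 1\} imply classification).
#' @param rowIds optional row identifiers (default `"r1"`, `"r2"`, ...).
#' @param provenance `"loaded"`, `"featurized"` or `"synthetic"`.
#' @param meta free-form metadata list.
#' @return A validated [MoleculeTable-class].
#' @export
#' @examples
#' X <- matrix(rbinom(20, 1, 0.5), 10, 2, dimnames = list(NULL, c("a", "b")))
#' MoleculeTable(X, labels = rbinom(10, 1, 0.5))
MoleculeTable <- function(features, labels, taskKind = NULL, rowIds = NULL,
                          provenance = "loaded", meta = list()) {
  features <- as.matrix(features)
  storage.mode(features) <- "double"
  labels <- as.numeric(labels)
  if (is.null(taskKind))
    taskKind <- if (all(labels %in% c(0, 1))) "classification" else "regression"
  if (is.null(rowIds)) rowIds <- paste0("r", seq_len(nrow(features)))
  new("MoleculeTable", features = features, labels = labels,
      taskKind = taskKind, rowIds = as.character(rowIds),
      provenance = provenance, meta = meta)
}

#' @rdname accessors
#' @export
setMethod("features", "MoleculeTable", function(object, ...) object@features)

#' @rdname accessors
#' @export
setMethod("labels", "MoleculeTable", function(object, ...) object@labels)

#' @rdname accessors
#' @export
setMethod("taskKind", "MoleculeTable", function(object, ...) object@taskKind)

#' @rdname accessors
#' @export
setMethod("featureNames", "MoleculeTable",
          function(object, ...) colnames(object@features))

#' @rdname accessors
#' @export
setMethod("rowIds", "MoleculeTable", function(object, ...) object@rowIds)

#' @describeIn MoleculeTable dimensions of the feature matrix.
#' @param x A `MoleculeTable`.
#' @export
setMethod("dim", "MoleculeTable", function(x) dim(x@features))

#' @describeIn MoleculeTable subset rows (`i`) and feature columns (`j`).
#' @param i,j row and column indices.
#' @param drop ignored; subsetting always returns a `MoleculeTable`.
#' @export
setMethod("[", "MoleculeTable", function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(nrow(x@features))
  if (missing(j)) j <- seq_len(ncol(x@features))
  new("MoleculeTable",
      features = x@features[i, j, drop = FALSE],
      labels = x@labels[i], taskKind = x@taskKind,
      rowIds = x@rowIds[i], provenance = x@provenance, meta = x@meta)
})

setMethod("show", "MoleculeTable", function(object) {
  cat(sprintf("MoleculeTable: %d samples x %d features (%s, %s)\n",
              nrow(object@features), ncol(object@features),
              object@taskKind, object@provenance))
  if (object@taskKind == "classification") {
    cat(sprintf("  positives: %d / %d\n",
                sum(object@labels == 1), length(object@labels)))
  } else {
    cat(sprintf("  label range: [%.4g, %.4g]\n",
                min(object@labels), max(object@labels)))
  }
  cat("  features:", paste(utils::head(colnames(object@features), 5),
                           collapse = ", "),
      if (ncol(object@features) > 5) "..." else "", "\n")
})

#' Write a MoleculeTable back to CSV
#'
#' Emits the validated table (features plus a label column) as an RFC-4180
#' comma-separated file with a header row. Integer-valued tables round-trip
#' exactly through [loadTable()].
#'
#' @param table A [MoleculeTable-class].
#' @param path Output file path.
#' @param labelColumn Name for the label column (default `"label"`).
#' @return `path`, invisibly.
#' @export
writeTable <- function(table, path, labelColumn = "label") {
  stopifnot(is(table, "MoleculeTable"))
  df <- as.data.frame(table@features)
  df[[labelColumn]] <- table@labels
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
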