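#' @include MoleculeTable-methods.R
NULL

#' Load and validate a tabular molecular dataset from CSV
#'
#' Reads a comma-separated file (header mandatory) containing either
#' precomputed numeric feature columns plus a label column, or a SMILES
#' column plus a label column in which case molecules are featurized into
#' the 167 MACCS keys via [maccsFeaturize()].
#'
#' Validation policy: rows with a missing label, an unparseable feature
#' value, or (when featurizing) an invalid SMILES are dropped, never
#' imputed; every dropped row is recorded with a reason code in
#' `meta(table)$dropLog`. The task kind is inferred from the surviving
#' labels (all values within \{0, 1\} implies classification) unless
#' `taskKind` overrides it.
#'
#' @param path CSV file path.
#' @param labelColumn name of the label column (default `"label"`).
#' @param smilesColumn optional name of a SMILES column; when given, all
#'   other non-label columns are ignored and features come from MACCS keys.
#' @param taskKind optional override, `"classification"` or `"regression"`.
#' @return A validated [MoleculeTable-class] with `provenance` `"loaded"`
#'   (or `"featurized"` when SMILES were featurized). The drop log is a
#'   data.frame with columns `row` and `reason` in `@meta$dropLog`.
#' @export
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write.csv(data.frame(f1 = c(0, 1, 1), f2 = c(1, 1, 0), label = c(0, 1, 1)),
#'           f, row.names = FALSE)
#' loadTable(f)
loadTable <- function(path, labelColumn = "label", smilesColumn = NULL,
                      taskKind = NULL) {
  if (!file.exists(path)) stop("input file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!labelColumn %in% names(df))
    stop("label column '", labelColumn, "' not present in ", path)

  drop_log <- data.frame(row = integer(0), reason = character(0))
  note_drop <- function(rows, reason) {
    if (length(rows))
      drop_log <<- rbind(drop_log, data.frame(row = rows, reason = reason))
  }

  labs <- suppressWarnings(as.numeric(df[[labelColumn]]))
  bad_label <- which(is.na(labs) | !nzchar(trimws(as.character(df[[labelColumn]]))))
  note_drop(bad_label, "missing_or_non_numeric_label")

  if (!is.null(smilesColumn)) {
    if (!smilesColumn %in% names(df))
      stop("SMILES column '", smilesColumn, "' not present in ", path)
    keep <- setdiff(seq_len(nrow(df)), bad_label)
    if (!length(keep)) stop("zero rows survived validation")
    fz <- maccsFeaturize(as.character(df[[smilesColumn]][keep]))
    note_drop(keep[fz$excluded], "invalid_smiles")
    keep <- keep[setdiff(seq_along(keep), fz$excluded)]
    if (!length(keep)) stop("zero rows survived validation")
    tab <- MoleculeTable(fz$features, labs[keep], taskKind = taskKind,
                         rowIds = paste0("r", keep), provenance = "featurized",
                         meta = list(dropLog = drop_log, source = path))
    .log(nrow(drop_log), " rows dropped while loading ", path)
    return(tab)
  }

  feat_cols <- setdiff(names(df), labelColumn)
  if (!length(feat_cols)) stop("no feature columns found")
  X <- suppressWarnings(
    vapply(feat_cols, function(cn) as.numeric(df[[cn]]), numeric(nrow(df))))
  if (nrow(df) == 1L) X <- matrix(X, nrow = 1L, dimnames = list(NULL, feat_cols))
  if (all(is.na(X)))
    stop("feature columns are non-numeric; supply smilesColumn to featurize")
  bad_feat <- setdiff(which(rowSums(is.na(X)) > 0), bad_label)
  note_drop(bad_feat, "non_numeric_or_missing_feature")
  keep <- setdiff(seq_len(nrow(df)), union(bad_label, bad_feat))
  if (!length(keep)) stop("zero rows survived validation")

  tab <- MoleculeTable(X[keep, , drop = FALSE], labs[keep],
                       taskKind = taskKind, rowIds = paste0("r", keep),
                       provenance = "loaded",
                       meta = list(dropLog = drop_log, source = path))
  .log(nrow(drop_log), " rows dropped while loading ", path)
  tab
}

# Fingerprint a single SMILES into the 166 standard MACCS bits, or NULL if
# the string does not parse. OpenBabel reports parse failures as errors and
# writes diagnostics to stderr; both are captured.
.maccs_one <- function(smi) {
  if (!nzchar(trimws(smi))) return(NULL)
  out <- tryCatch(
    suppressWarnings(suppressMessages(
      ChemmineOB::fingerprint_OB(
        ChemmineOB::forEachMol("SMILES", smi, identity), "MACCS"))),
    error = function(e) NULL)
  if (is.null(out)) return(NULL)
  as.numeric(out)[seq_len(166)]
}

#' Featurize SMILES strings into MACCS keys
#'
#' Converts molecules to the standard 167-position MACCS key fingerprint:
#' one binary column per key, answering a structural yes/no question. Key 0
#' is the conventional placeholder bit and is always 0; keys 1-166 are
#' computed by substructure matching (OpenBabel's MACCS definitions, whose
#' key numbering matches the RDKit convention). Invalid SMILES are excluded
#' with a warning listing their indices.
#'
#' @param smiles character vector of SMILES strings.
#' @return list with `features` (binary matrix, one row per valid molecule,
#'   167 columns named `MACCS_0` ... `MACCS_166`), `excluded` (integer
#'   indices of invalid inputs) and `smiles` (the retained strings).
#' @export
#' @examples
#' fp <- maccsFeaturize("CCO")
#' dim(fp$features)   # 1 x 167
maccsFeaturize <- function(smiles) {
  smiles <- as.character(smiles)
  if (!length(smiles)) stop("no valid molecules: empty SMILES input")
  bits <- lapply(smiles, .maccs_one)
  excluded <- which(vapply(bits, is.null, logical(1)))
  keep <- setdiff(seq_along(smiles), excluded)
  if (!length(keep)) stop("no valid molecules in SMILES input")
  if (length(excluded))
    warning("excluded ", length(excluded), " invalid SMILES at indices: ",
            paste(excluded, collapse = ", "))
  X <- cbind(0, do.call(rbind, bits[keep]))
  colnames(X) <- paste0("MACCS_", 0:166)
  rownames(X) <- NULL
  list(features = X, excluded = excluded, smiles = smiles[keep])
}

#' The standard MACCS key description catalog
#'
#' Loads the packaged catalog of human-readable descriptions for the 167
#' MACCS keys (key 0 is the conventional placeholder). Feature names follow
#' the `MACCS_<k>` convention produced by [maccsFeaturize()].
#'
#' @return A [FeatureCatalog-class] with `sourceTag = "maccs_standard"`.
#' @export
#' @examples
#' humanizeFeatures("MACCS_85", maccsCatalog())  # tertiary amine key
maccsCatalog <- function() {
  path <- system.file("extdata", "maccs_keys.csv", package = "chemxplain",
                      mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  entries <- stats::setNames(df$description, paste0("MACCS_", df$key))
  new("FeatureCatalog", entries = entries, sourceTag = "maccs_standard")
}

#' Build a feature catalog from user-supplied descriptions
#'
#' @param entries named character vector mapping feature names to
#'   human-readable descriptions; may be empty for pure passthrough.
#' @return A [FeatureCatalog-class].
#' @export
featureCatalog <- function(entries = character(0)) {
  new("FeatureCatalog", entries = entries,
      sourceTag = if (length(entries)) "user_supplied" else "passthrough")
}

#' Resolve feature names to human-readable descriptions
#'
#' Total function: every input name resolves, in order. Names present in
#' the catalog map to their descriptions; unknown names fall back to the
#' name itself with a logged warning (passthrough).
#'
#' @param names character vector of feature names.
#' @param catalog A [FeatureCatalog-class].
#' @return character vector of descriptions, same length and order.
#' @export
humanizeFeatures <- function(names, catalog = featureCatalog()) {
  stopifnot(is(catalog, "FeatureCatalog"))
  if (!length(names)) return(character(0))
  out <- unname(catalog@entries[names])
  miss <- is.na(out)
  if (any(miss)) {
    .log("no catalog description for: ", paste(names[miss], collapse = ", "))
    out[miss] <- names[miss]
  }
  out
}
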