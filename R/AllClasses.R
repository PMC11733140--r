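#' @include AllGenerics.R
NULL

#' MoleculeTable: a validated feature matrix with target labels
#'
#' The central tabular container: an \eqn{n \times d} numeric feature matrix
#' with unique feature names, a length-\eqn{n} label vector, and the task
#' kind. Classification labels are restricted to \{0, 1\}; no missing values
#' survive validation.
#'
#' @slot features numeric matrix (rows = molecules/samples, columns = features).
#' @slot labels numeric target vector.
#' @slot taskKind `"classification"` or `"regression"`.
#' @slot rowIds character identifiers, unique per row.
#' @slot provenance one of `"loaded"`, `"featurized"`, `"synthetic"`.
#' @slot meta list of free-form metadata (drop log, source path, ...).
#' @seealso [loadTable()], [maccsFeaturize()], [generateSynthetic()]
#' @export
setClass("MoleculeTable",
  slots = c(features = "matrix", labels = "numeric", taskKind = "character",
            rowIds = "character", provenance = "character", meta = "list"))

setValidity("MoleculeTable", function(object) {
  f <- object@features
  msg <- character(0)
  if (nrow(f) < 1L || ncol(f) < 1L) msg <- c(msg, "need n >= 1 and d >= 1")
  nm <- colnames(f)
  if (is.null(nm) || anyDuplicated(nm) || any(!nzchar(nm)))
    msg <- c(msg, "feature names must be unique and nonempty")
  if (!is.numeric(f) || anyNA(f) || any(!is.finite(f)))
    msg <- c(msg, "features must be finite numeric with no missing values")
  if (length(object@labels) != nrow(f))
    msg <- c(msg, "labels length must equal nrow(features)")
  if (anyNA(object@labels)) msg <- c(msg, "labels must not contain NA")
  if (!object@taskKind %in% c("classification", "regression"))
    msg <- c(msg, "taskKind must be 'classification' or 'regression'")
  if (object@taskKind == "classification" &&
      !all(object@labels %in% c(0, 1)))
    msg <- c(msg, "classification labels must take values in {0, 1}")
  if (length(object@rowIds) != nrow(f) || anyDuplicated(object@rowIds))
    msg <- c(msg, "rowIds must be unique, one per row")
  if (!object@provenance %in% c("loaded", "featurized", "synthetic"))
    msg <- c(msg, "provenance must be loaded/featurized/synthetic")
  if (length(msg)) msg else TRUE
})

#' FeatureCatalog: human-readable descriptions for feature names
#'
#' Maps raw feature identifiers (e.g. MACCS key names) to human-readable
#' descriptions used in prompts, plots and reports. Lookups for unknown
#' names fall back to the name itself (passthrough), so resolution is total.
#'
#' @slot entries named character vector: feature name -> description.
#' @slot sourceTag `"maccs_standard"`, `"user_supplied"` or `"passthrough"`.
#' @seealso [maccsCatalog()], [humanizeFeatures()]
#' @export
setClass("FeatureCatalog",
  slots = c(entries = "character", sourceTag = "character"))

setValidity("FeatureCatalog", function(object) {
  if (length(object@entries) &&
      (is.null(names(object@entries)) || any(!nzchar(names(object@entries)))))
    return("entries must be a named character vector")
  if (!object@sourceTag %in% c("maccs_standard", "user_supplied", "passthrough"))
    return("sourceTag must be maccs_standard/user_supplied/passthrough")
  TRUE
})

#' SyntheticSpec: parameters of the planted-structure generator
#'
#' Describes a synthetic binary-feature dataset with a sparse planted
#' linear (regression) or logistic (classification) feature-label
#' relationship. Identical spec + seed reproduces the table exactly.
#' Support indices are 1-based (R convention).
#'
#' @slot n integer, number of rows.
#' @slot d integer, number of Bernoulli(0.5) binary features.
#' @slot support integer vector of truly associated feature indices (1-based).
#' @slot weights signed numeric weights, one per support index.
#' @slot noiseSd non-negative noise standard deviation (regression only).
#' @slot taskKind `"classification"` or `"regression"`.
#' @slot seed integer RNG seed.
#' @seealso [generateSynthetic()]
#' @export
setClass("SyntheticSpec",
  slots = c(n = "integer", d = "integer", support = "integer",
            weights = "numeric", noiseSd = "numeric", taskKind = "character",
            seed = "integer"))

setValidity("SyntheticSpec", function(object) {
  msg <- character(0)
  if (object@n < 1L || object@d < 1L) msg <- c(msg, "need n >= 1, d >= 1")
  if (length(object@support) > object@d) msg <- c(msg, "|support| must be <= d")
  if (length(object@support) &&
      (min(object@support) < 1L || max(object@support) > object@d))
    msg <- c(msg, "support indices must lie in 1..d")
  if (anyDuplicated(object@support)) msg <- c(msg, "support indices must be distinct")
  if (length(object@weights) != length(object@support))
    msg <- c(msg, "weights must match support length")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  if (!object@taskKind %in% c("classification", "regression"))
    msg <- c(msg, "taskKind must be 'classification' or 'regression'")
  if (length(msg)) msg else TRUE
})

#' SurrogateModel: fitted gradient-boosted-tree surrogate
#'
#' Wraps a fitted XGBoost booster together with the frozen feature schema,
#' task kind, split seed and the hardcoded hyperparameter set, so that
#' prediction and attribution can validate inputs by name.
#'
#' @slot booster the fitted `xgb.Booster` handle.
#' @slot taskKind `"classification"` or `"regression"`.
#' @slot featureNames ordered feature names frozen at fit time.
#' @slot splitSeed integer seed that produced the train/holdout split.
#' @slot hyperparameters named list (read-only audit record).
#' @slot trainIds,testIds row ids of the training and holdout partitions.
#' @seealso [fitSurrogate()], [predict,SurrogateModel-method]
#' @export
setClass("SurrogateModel",
  slots = c(booster = "ANY", taskKind = "character",
            featureNames = "character", splitSeed = "integer",
            hyperparameters = "list", trainIds = "character",
            testIds = "character"))

#' EvalReport: holdout evaluation of a surrogate model
#'
#' Holdout-only metrics plus the paired (truth, prediction) vectors that
#' back the error/parity plot. Regression reports RMSE and R-squared;
#' classification reports accuracy and F1 (positive class = 1).
#'
#' @slot taskKind task kind of the evaluated model.
#' @slot metrics named list of metric values.
#' @slot truth,predicted holdout label and prediction vectors.
#' @slot trainSize,testSize partition sizes (sum to n).
#' @seealso [fitSurrogate()], [exportEvalPlot()]
#' @export
setClass("EvalReport",
  slots = c(taskKind = "character", metrics = "list", truth = "numeric",
            predicted = "numeric", trainSize = "integer", testSize = "integer"))

#' LocalAttribution: per-row, per-feature local explanation values
#'
#' For tree SHAP, `values[i, j]` is the interventional Shapley contribution
#' of feature j to row i's prediction (margin space for classification) and
#' `baseValues[i] + sum(values[i, ])` equals the model prediction (local
#' accuracy). For LIME, `values` holds per-row local linear surrogate
#' weights and `baseValues` the local intercepts.
#'
#' @slot values numeric n x d matrix of signed attributions.
#' @slot baseValues numeric length-n vector.
#' @slot method `"tree_shap"` or `"lime"`.
#' @slot sampleRowIds ids of the attributed rows.
#' @slot metadata list: attribution space, background size, kernel width, ...
#' @seealso [localTreeShap()], [localLime()], [globalize()]
#' @export
setClass("LocalAttribution",
  slots = c(values = "matrix", baseValues = "numeric", method = "character",
            sampleRowIds = "character", metadata = "list"))

setValidity("LocalAttribution", function(object) {
  msg <- character(0)
  if (any(!is.finite(object@values))) msg <- c(msg, "values must be finite")
  if (!object@method %in% c("tree_shap", "lime"))
    msg <- c(msg, "method must be tree_shap or lime")
  if (nrow(object@values) != length(object@baseValues))
    msg <- c(msg, "baseValues length must equal nrow(values)")
  if (length(msg)) msg else TRUE
})

#' GlobalImportance: dataset-level feature importance with direction calls
#'
#' Aggregates local attributions into one record per feature: a
#' non-negative global score (mean absolute attribution for SHAP; the
#' positive part of the cross-feature Z-score for LIME), a direction call
#' from the sign of the mean signed attribution with a relative dead-band,
#' and a rank (1 = most important, ties broken by feature name).
#'
#' @slot table data.frame with columns feature, score, zscore, meanSigned,
#'   direction, rank.
#' @slot method `"tree_shap"` or `"lime"`.
#' @seealso [globalize()], [topFeatures()], [exportImportancePlot()]
#' @export
setClass("GlobalImportance",
  slots = c(table = "data.frame", method = "character"))

setValidity("GlobalImportance", function(object) {
  tb <- object@table
  need <- c("feature", "score", "zscore", "meanSigned", "direction", "rank")
  if (!all(need %in% names(tb))) return("table missing required columns")
  if (any(tb$score < 0)) return("scores must be >= 0")
  if (!setequal(tb$rank, seq_len(nrow(tb)))) return("ranks must be a permutation of 1..d")
  if (!all(tb$direction %in% c("positive", "negative", "unclear")))
    return("direction must be positive/negative/unclear")
  TRUE
})

#' RetrievalConfig: chunking, embedding and MMR parameters
#'
#' @slot chunkSize chunk window in characters (default 1000).
#' @slot chunkOverlap overlap between consecutive chunks (default 200);
#'   must be smaller than `chunkSize`.
#' @slot lambda MMR relevance-diversity trade-off in \[0, 1\] (default 0.5).
#' @slot kRetrieve excerpts retrieved per query (default 4).
#' @slot embedDim dimensionality of the hashed TF-IDF embedding (default 512).
#' @slot embedder embedder tag; `"hashed_tfidf"` is the offline default.
#' @seealso [retrievalConfig()], [indexCorpus()]
#' @export
setClass("RetrievalConfig",
  slots = c(chunkSize = "integer", chunkOverlap = "integer",
            lambda = "numeric", kRetrieve = "integer",
            embedDim = "integer", embedder = "character"))

setValidity("RetrievalConfig", function(object) {
  msg <- character(0)
  if (object@lambda < 0 || object@lambda > 1) msg <- c(msg, "lambda must be in [0, 1]")
  if (object@chunkOverlap >= object@chunkSize)
    msg <- c(msg, "chunkOverlap must be smaller than chunkSize")
  if (object@chunkSize < 1L || object@kRetrieve < 1L || object@embedDim < 2L)
    msg <- c(msg, "chunkSize, kRetrieve, embedDim must be positive")
  if (length(msg)) msg else TRUE
})

#' CorpusIndex: chunked, embedded literature corpus
#'
#' Holds the ingested documents, their overlapping character-span chunks,
#' the L2-normalised hashed TF-IDF chunk vectors and the corpus IDF weights
#' needed to embed queries consistently.
#'
#' @slot documents data.frame: doc_id, source, title, nchar.
#' @slot chunks data.frame: doc_id, chunk_index, text, start, end.
#' @slot vectors numeric matrix, one row per chunk.
#' @slot idf numeric IDF vector of length `embedDim`.
#' @slot config the [RetrievalConfig-class] used to build the index.
#' @seealso [ingestCorpus()], [indexCorpus()], [retrieveForFeature()]
#' @export
setClass("CorpusIndex",
  slots = c(documents = "data.frame", chunks = "data.frame",
            vectors = "matrix", idf = "numeric", config = "RetrievalConfig"))

#' RetrievalResult: MMR-selected excerpts for one query
#'
#' @slot query the query string.
#' @slot chunks data.frame of the selected chunks (doc_id, chunk_index,
#'   text, similarity) in MMR selection order.
#' @slot lowConfidence TRUE when no candidate showed non-trivial similarity.
#' @seealso [retrieveForFeature()]
#' @export
setClass("RetrievalResult",
  slots = c(query = "character", chunks = "data.frame",
            lowConfidence = "logical"))

#' PromptBundle: the stuffed chain-of-thought prompt
#'
#' Deterministic rendering of the per-feature evidence blocks plus the
#' chain-of-thought task instructions. Features with no retrieved evidence
#' carry an explicit `NO_EVIDENCE` marker so the generator can emit the
#' disclaimer instead of inventing support.
#'
#' @slot preamble system preamble text.
#' @slot blocks list of per-feature blocks (description, direction, excerpts).
#' @slot instructions task instruction text.
#' @slot templateVersion template version id recorded in outputs.
#' @slot property target property name.
#' @seealso [assemblePrompt()], [promptText()]
#' @export
setClass("PromptBundle",
  slots = c(preamble = "character", blocks = "list",
            instructions = "character", templateVersion = "character",
            property = "character"))

#' GenerationBackend: pluggable text-generation contract
#'
#' A backend is a name plus a `generate(prompt, seed)` function and a
#' determinism flag. The built-in mock backend is fully deterministic:
#' identical (prompt, seed) yields identical text.
#'
#' @slot name backend name.
#' @slot generator function(prompt, seed) -> character text.
#' @slot deterministic logical determinism declaration.
#' @seealso [mockBackend()], [generateExplanations()]
#' @export
setClass("GenerationBackend",
  slots = c(name = "character", generator = "function",
            deterministic = "logical"))

#' Explanation: one generated, parsed and cited explanation
#'
#' @slot runId run identifier (seed-derived).
#' @slot text the full generated text.
#' @slot hypotheses data.frame: feature, description, direction
#'   (positive/negative/unclear), supported (logical).
#' @slot citations data.frame: key, doc_id, chunk_index, feature, resolved.
#' @seealso [generateExplanations()], [attachCitations()]
#' @export
setClass("Explanation",
  slots = c(runId = "character", text = "character",
            hypotheses = "data.frame", citations = "data.frame"))

#' HypothesisTally: per-feature direction counts across repeated runs
#'
#' `counts` is an \eqn{N_{features} \times 3} matrix of positive, negative
#' and unclear direction labels collected over `nRuns` generation runs;
#' each row sums to `nRuns` (features absent from a run count as unclear).
#'
#' @slot counts integer matrix with columns positive, negative, unclear.
#' @slot nRuns number of runs tallied.
#' @seealso [tallyHypotheses()], [hypothesisPrecision()]
#' @export
setClass("HypothesisTally",
  slots = c(counts = "matrix", nRuns = "integer"))

setValidity("HypothesisTally", function(object) {
  cts <- object@counts
  if (!all(colnames(cts) == c("positive", "negative", "unclear")))
    return("counts columns must be positive, negative, unclear")
  if (any(cts < 0)) return("counts must be >= 0")
  if (!all(rowSums(cts) == object@nRuns))
    return("per-feature counts must sum to nRuns")
  TRUE
})
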