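#' @include utils.R
NULL

#' Accessors for chemxplain data objects
#'
#' Small generic accessor family used across the package's S4 classes.
#' `features()` returns the numeric feature matrix, `labels()` the target
#' vector, `taskKind()` the modelling task (`"classification"` or
#' `"regression"`), and `featureNames()` the ordered feature identifiers.
#'
#' @param object A chemxplain S4 object.
#' @param ... Additional arguments passed to methods.
#' @return The slot contents; see the individual class documentation.
#' @name accessors
#' @aliases features labels taskKind featureNames
#' @examples
#' tab <- generateSynthetic(syntheticSpec(n = 20, d = 4, support = 1,
#'                                        weights = 2, seed = 1))
#' dim(features(tab))
#' taskKind(tab)
NULL

#' @rdname accessors
#' @export
setGeneric("features", function(object, ...) standardGeneric("features"))

#' @rdname accessors
#' @export
setGeneric("labels", function(object, ...) standardGeneric("labels"))

#' @rdname accessors
#' @export
setGeneric("taskKind", function(object, ...) standardGeneric("taskKind"))

#' @rdname accessors
#' @export
setGeneric("featureNames", function(object, ...) standardGeneric("featureNames"))

#' @rdname accessors
#' @export
setGeneric("rowIds", function(object, ...) standardGeneric("rowIds"))

#' @rdname globalize
#' @export
setGeneric("globalize", function(object, ...) standardGeneric("globalize"))

#' Extract the ordered per-feature importance table
#'
#' @param object A [GlobalImportance-class].
#' @param ... unused.
#' @return data.frame ordered by rank (feature, score, zscore, meanSigned,
#'   direction, rank).
#' @export
setGeneric("importanceTable", function(object, ...) standardGeneric("importanceTable"))

#' @rdname promptText
#' @export
setGeneric("promptText", function(object, ...) standardGeneric("promptText"))

#' Invoke a text-generation backend
#'
#' Dispatches to the backend's `generate(prompt, seed)` contract; the
#' deterministic mock backend returns identical text for identical
#' (prompt, seed).
#'
#' @param backend A [GenerationBackend-class].
#' @param prompt prompt text, usually from [promptText()].
#' @param seed integer seed for this run.
#' @param ... unused.
#' @return generated text (character scalar).
#' @export
setGeneric("generate", function(backend, prompt, seed, ...) standardGeneric("generate"))
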