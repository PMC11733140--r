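#' @include explanation.R
NULL

#' Tally hypothesis directions across repeated runs
#'
#' Counts, for every feature of the shared feature set, how many runs
#' labelled its correlation positive, negative, or unclear. Features
#' absent from a run count as unclear for that run, so each feature's
#' counts sum to the number of runs.
#'
#' @param explanations nonempty list of [Explanation-class] sharing one
#'   feature set.
#' @return A [HypothesisTally-class].
#' @export
tallyHypotheses <- function(explanations) {
  if (!length(explanations)) stop("empty explanation list")
  feats <- explanations[[1]]@hypotheses$feature
  counts <- matrix(0L, length(feats), 3,
                   dimnames = list(feats, c("positive", "negative", "unclear")))
  for (ex in explanations) {
    hyp <- ex@hypotheses
    for (f in feats) {
      k <- match(f, hyp$feature)
      dir <- if (is.na(k)) "unclear" else hyp$direction[k]
      if (!dir %in% colnames(counts)) dir <- "unclear"
      counts[f, dir] <- counts[f, dir] + 1L
    }
  }
  new("HypothesisTally", counts = counts, nRuns = length(explanations))
}

#' Hypothesis precision across repeated runs
#'
#' The consistency score over \eqn{N_{runs}} generation runs with
#' per-label weights +1 (positive), -1 (negative) and 0 (unclear):
#' \deqn{precision = \frac{1}{N_{features} N_{runs}}
#'   \sum_i |n_{i,positive} - n_{i,negative}|.}
#' Bounded in \[0, 1\]: 0 when every label is unclear, 1 when every run
#' assigns every feature one consistent non-unclear direction.
#'
#' @param tally A [HypothesisTally-class].
#' @return list with `precision` and `perFeature` (the per-feature
#'   \eqn{|n_{pos} - n_{neg}|} contributions).
#' @export
hypothesisPrecision <- function(tally) {
  stopifnot(is(tally, "HypothesisTally"))
  validObject(tally)
  if (nrow(tally@counts) < 1L || tally@nRuns < 1L)
    stop("need at least one feature and one run")
  contrib <- abs(tally@counts[, "positive"] - tally@counts[, "negative"])
  list(precision = sum(contrib) / (nrow(tally@counts) * tally@nRuns),
       perFeature = contrib)
}

#' Longest common subsequence length over whitespace tokens
#'
#' Standard dynamic program; the ROUGE-L substrate.
#'
#' @param a,b character scalars (tokenized on whitespace) or token vectors.
#' @return integer LCS length.
#' @export
lcsLength <- function(a, b) {
  ta <- if (length(a) == 1L) .ws_tokens(a) else a
  tb <- if (length(b) == 1L) .ws_tokens(b) else b
  na <- length(ta); nb <- length(tb)
  if (na == 0L || nb == 0L) return(0L)
  prev <- integer(nb + 1L)
  for (i in seq_len(na)) {
    cur <- integer(nb + 1L)
    for (j in seq_len(nb)) {
      cur[j + 1L] <- if (ta[i] == tb[j]) prev[j] + 1L
                     else max(prev[j + 1L], cur[j])
    }
    prev <- cur
  }
  prev[nb + 1L]
}

#' ROUGE-L score between two texts
#'
#' Token-level ROUGE-L with whitespace tokenization and the F1 (beta = 1)
#' convention: \eqn{R = LCS/|reference|}, \eqn{P = LCS/|candidate|},
#' \eqn{F = 2RP/(R+P)} (0 when \eqn{R+P = 0}). Empty texts score (0,0,0).
#'
#' @param candidate,reference texts to compare.
#' @return named numeric vector `c(recall, precision, f)`.
#' @export
rougeL <- function(candidate, reference) {
  tc <- .ws_tokens(candidate); tr <- .ws_tokens(reference)
  if (!length(tc) || !length(tr))
    return(c(recall = 0, precision = 0, f = 0))
  lcs <- lcsLength(tc, tr)
  r <- lcs / length(tr); p <- lcs / length(tc)
  f <- if (r + p > 0) 2 * r * p / (r + p) else 0
  c(recall = r, precision = p, f = f)
}

#' ROUGE-L variability across repeated runs
#'
#' Computes the ROUGE-L F score over all unordered pairs of generated
#' explanations and reports the pairwise table with its mean and standard
#' deviation — the repeated-run variability protocol (5 runs by default
#' upstream).
#'
#' @param explanations list (length >= 2) of [Explanation-class] or
#'   character texts.
#' @return list with `pairs` (data.frame i, j, lcs, recall, precision, f),
#'   `mean` and `sd`.
#' @export
rougeVariability <- function(explanations) {
  texts <- vapply(explanations, function(e)
    if (is(e, "Explanation")) e@text else as.character(e), character(1))
  n <- length(texts)
  if (n < 2L) stop("need at least 2 explanations")
  rows <- list()
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    sc <- rougeL(texts[i], texts[j])
    rows[[length(rows) + 1L]] <- data.frame(
      i = i, j = j, lcs = lcsLength(texts[i], texts[j]),
      recall = sc["recall"], precision = sc["precision"], f = sc["f"],
      row.names = NULL)
  }
  pairs <- do.call(rbind, rows)
  list(pairs = pairs, mean = mean(pairs$f),
       sd = if (nrow(pairs) > 1L) stats::sd(pairs$f) else 0)
}

#' Structural audit of explanation citations
#'
#' For every citation attached to the explanations: `resolved` iff the
#' cited document id is registered in the corpus index, and `supported`
#' iff the cited chunk's text contains the feature's description or a
#' declared catalog synonym (case-insensitive substring; a deliberately
#' structural criterion — semantic entailment is out of scope). Reports
#' raw counts and per-explanation normalised accuracy side by side.
#'
#' @param explanations list of [Explanation-class] after
#'   [attachCitations()].
#' @param index A [CorpusIndex-class].
#' @param catalog A [FeatureCatalog-class] used to resolve descriptions.
#' @return list with `citations` (audit data.frame), `correct`, `total`,
#'   `accuracy` (correct/total over all citations, NA when no citations)
#'   and `perExplanation` (normalised accuracy per run, then averaged).
#' @export
auditCitations <- function(explanations, index, catalog = featureCatalog()) {
  stopifnot(is(index, "CorpusIndex"))
  rows <- list()
  per_expl <- numeric(0)
  for (ei in seq_along(explanations)) {
    ex <- explanations[[ei]]
    ct <- ex@citations
    if (!nrow(ct)) next
    for (k in seq_len(nrow(ct))) {
      resolved <- isTRUE(ct$resolved[k])
      supported <- FALSE
      if (resolved && !is.na(ct$feature[k])) {
        desc <- humanizeFeatures(ct$feature[k], catalog)
        hit <- index@chunks$doc_id == ct$doc_id[k] &
          index@chunks$chunk_index == ct$chunk_index[k]
        if (any(hit))
          supported <- grepl(tolower(desc),
                             tolower(index@chunks$text[which(hit)[1]]),
                             fixed = TRUE)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        explanation = ei, key = ct$key[k], doc_id = ct$doc_id[k],
        chunk_index = ct$chunk_index[k], feature = ct$feature[k],
        resolved = resolved, supported = supported,
        stringsAsFactors = FALSE)
    }
    audited <- vapply(rows, function(r) r$explanation == ei, logical(1))
    ok <- vapply(rows[audited], function(r) r$resolved && r$supported,
                 logical(1))
    per_expl <- c(per_expl, mean(ok))
  }
  citations <- if (length(rows)) do.call(rbind, rows) else
    data.frame(explanation = integer(0), key = character(0),
               doc_id = character(0), chunk_index = integer(0),
               feature = character(0), resolved = logical(0),
               supported = logical(0), stringsAsFactors = FALSE)
  total <- nrow(citations)
  correct <- sum(citations$resolved & citations$supported)
  list(citations = citations, correct = correct, total = total,
       accuracy = if (total) correct / total else NA_real_,
       perExplanation = if (length(per_expl)) mean(per_expl) else NA_real_)
}
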