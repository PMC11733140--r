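#' @include MoleculeTable-methods.R
NULL

#' Specify a synthetic dataset with a planted feature-label relationship
#'
#' Convenience constructor for [SyntheticSpec-class]. Features are
#' independent Bernoulli(0.5) bits; the label depends only on the planted
#' `support` features through a linear form \eqn{\eta_i = \sum_{j \in S} w_j
#' x_{ij}}. Regression adds Gaussian noise (`noiseSd`); classification
#' draws \eqn{y_i \sim Bernoulli(logistic(\eta_i + b))} with the intercept
#' `b` chosen so the marginal positive rate is approximately 0.5.
#'
#' @param n number of rows.
#' @param d number of binary features (named `f1` ... `fd`).
#' @param support 1-based indices of truly associated features.
#' @param weights signed weights, one per support index.
#' @param noiseSd noise standard deviation, >= 0 (regression only).
#' @param taskKind `"regression"` (default) or `"classification"`.
#' @param seed integer RNG seed; identical spec + seed reproduces the table.
#' @return A [SyntheticSpec-class].
#' @export
#' @examples
#' syntheticSpec(n = 2000, d = 20, support = c(3, 8, 14),
#'               weights = c(1.5, -1.5, 1.5), noiseSd = 0.1, seed = 1)
syntheticSpec <- function(n, d, support = integer(0), weights = numeric(0),
                          noiseSd = 0, taskKind = "regression", seed = 1L) {
  new("SyntheticSpec", n = as.integer(n), d = as.integer(d),
      support = as.integer(support), weights = as.numeric(weights),
      noiseSd = as.numeric(noiseSd), taskKind = taskKind,
      seed = as.integer(seed))
}

#' Generate a synthetic MoleculeTable from a spec
#'
#' Draws the binary feature matrix and labels described by the spec. With
#' `noiseSd = 0` and regression, labels equal the planted linear form
#' exactly, which downstream tests exploit as a closed-form oracle.
#'
#' @param spec A [SyntheticSpec-class].
#' @return A [MoleculeTable-class] with `provenance = "synthetic"`; the
#'   spec is retained in `@meta$spec`.
#' @export
#' @examples
#' tab <- generateSynthetic(syntheticSpec(n = 100, d = 5, support = 1,
#'                                        weights = 2, seed = 1))
#' all(labels(tab) == 2 * features(tab)[, 1])
generateSynthetic <- function(spec) {
  stopifnot(is(spec, "SyntheticSpec"))
  validObject(spec)
  .with_seed(spec@seed, {
    X <- matrix(stats::rbinom(spec@n * spec@d, 1L, 0.5), spec@n, spec@d)
    colnames(X) <- paste0("f", seq_len(spec@d))
    eta <- as.numeric(X[, spec@support, drop = FALSE] %*% spec@weights)
    if (spec@taskKind == "regression") {
      y <- eta + if (spec@noiseSd > 0)
        stats::rnorm(spec@n, 0, spec@noiseSd) else 0
    } else {
      b <- -0.5 * sum(spec@weights)   # centres the logit: P(y = 1) ~ 0.5
      y <- stats::rbinom(spec@n, 1L, stats::plogis(eta + b))
    }
    MoleculeTable(X, y, taskKind = spec@taskKind,
                  rowIds = sprintf("s%0*d", nchar(spec@n), seq_len(spec@n)),
                  provenance = "synthetic", meta = list(spec = spec))
  })
}

# Filler sentences shared by all synthetic documents; deliberately neutral
# so only the claim sentence carries a direction keyword.
.filler <- c(
  "The dataset was curated from previously published measurements.",
  "Experimental protocols followed standard laboratory practice.",
  "Molecular descriptors were computed for every compound in the series.",
  "Statistical significance was assessed with appropriate controls.",
  "Further mechanistic investigations are ongoing.")

#' Write a toy literature corpus with directional feature-property claims
#'
#' Generates a directory of short plain-text documents for end-to-end
#' testing of retrieval, generation and the citation audit. One document is
#' written per supported feature, asserting a directional claim in
#' controlled vocabulary ("increases"/"decreases" the property); optional
#' distractor documents discuss unrelated topics and never mention the
#' features. Each document has a title line containing an author token and
#' a year, so rendered citations are well-formed.
#'
#' @param descriptions character vector of feature descriptions to assert
#'   claims about.
#' @param directions `"positive"` or `"negative"`, one per description.
#' @param property target property name used in the claims.
#' @param dir output directory (created if needed).
#' @param nDistractors number of distractor documents (default 2).
#' @param seed RNG seed controlling filler selection.
#' @return The directory path, invisibly; one `.txt` file per document.
#' @export
#' @examples
#' d <- tempfile(); syntheticCorpus("tertiary amine", "positive",
#'                                  "toxicity", d)
#' list.files(d)
syntheticCorpus <- function(descriptions, directions, property, dir,
                            nDistractors = 2, seed = 1L) {
  stopifnot(length(descriptions) == length(directions),
            all(directions %in% c("positive", "negative")))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  authors <- c("Rivera", "Okafor", "Lindgren", "Tanaka", "Moreau", "Szabo",
               "Almeida", "Novak")
  .with_seed(seed, {
    for (i in seq_along(descriptions)) {
      verb <- if (directions[i] == "positive") "increases" else "decreases"
      title <- sprintf("%s et al. (20%02d) On the role of %s in %s",
                       authors[(i - 1L) %% length(authors) + 1L],
                       10 + i, descriptions[i], property)
      claim <- sprintf(
        "Our measurements demonstrate that the presence of %s %s %s across the studied series.",
        descriptions[i], verb, property)
      body <- c(title, "", sample(.filler, 3), claim, sample(.filler, 2))
      writeLines(body, file.path(dir, sprintf("study_%02d.txt", i)))
    }
    for (k in seq_len(nDistractors)) {
      title <- sprintf("%s et al. (20%02d) Advances in unrelated instrumentation",
                       authors[(length(descriptions) + k - 1L) %% length(authors) + 1L],
                       20 + k)
      body <- c(title, "",
                "This report concerns calibration of spectrometer hardware.",
                sample(.filler, 3))
      writeLines(body, file.path(dir, sprintf("distractor_%02d.txt", k)))
    }
  })
  invisible(dir)
}
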