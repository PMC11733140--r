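#' @include attribution.R
NULL

#' Aggregate local attributions into global feature importance
#'
#' Turns an \eqn{n \times d} local attribution matrix into one record per
#' feature. For tree SHAP the global score is the mean absolute attribution
#' \eqn{G_j = \frac{1}{n}\sum_i |\phi_{ij}|}. For LIME, the mean absolute
#' local weights \eqn{s_j} are standardised across features into Z-scores
#' \eqn{z_j = (s_j - \bar{s}) / sd(s)}; the score is \eqn{\max(z_j, 0)} and
#' ranking follows \eqn{z_j}. The direction call compares the mean signed
#' attribution to a relative dead-band \eqn{\delta = 0.01 \max_j G_j}:
#' above \eqn{+\delta} is positive, below \eqn{-\delta} negative, else
#' unclear. Ties in rank break by lexicographic feature name.
#'
#' Scores are invariant to row order; degenerate LIME inputs whose
#' per-feature scores are all equal (zero spread) get all-zero Z-scores
#' with a warning.
#'
#' @param object A [LocalAttribution-class] with at least one row.
#' @param ... unused.
#' @return A [GlobalImportance-class].
#' @name globalize
#' @aliases globalize,LocalAttribution-method
#' @export
setMethod("globalize", "LocalAttribution", function(object, ...) {
  phi <- object@values
  if (nrow(phi) == 0L) stop("cannot globalize an empty attribution")
  s <- colMeans(abs(phi))
  meanSigned <- colMeans(phi)
  if (object@method == "lime") {
    spread <- stats::sd(s)
    if (is.na(spread) || spread == 0) {
      warning("all per-feature LIME scores are equal; Z-scores set to 0")
      z <- rep(0, length(s))
    } else {
      z <- (s - mean(s)) / spread
    }
    score <- pmax(z, 0)
    rank_key <- z
  } else {
    score <- s
    z <- if (length(s) > 1L && stats::sd(s) > 0)
      (s - mean(s)) / stats::sd(s) else rep(0, length(s))
    rank_key <- score
  }
  delta <- 0.01 * max(score)
  direction <- ifelse(meanSigned > delta, "positive",
                      ifelse(meanSigned < -delta, "negative", "unclear"))
  ord <- order(-rank_key, colnames(phi))
  rank <- integer(length(s))
  rank[ord] <- seq_along(ord)
  tb <- data.frame(feature = colnames(phi), score = unname(score),
                   zscore = unname(z), meanSigned = unname(meanSigned),
                   direction = unname(direction), rank = rank,
                   stringsAsFactors = FALSE)
  new("GlobalImportance", table = tb, method = object@method)
})

#' @rdname importanceTable
#' @export
setMethod("importanceTable", "GlobalImportance", function(object, ...) {
  tb <- object@table
  tb[order(tb$rank), , drop = FALSE]
})

setMethod("show", "GlobalImportance", function(object) {
  cat(sprintf("GlobalImportance (%s), %d features\n", object@method,
              nrow(object@table)))
  print(utils::head(importanceTable(object), 5), row.names = FALSE)
})

#' Select the top-k impactful features
#'
#' Returns the k highest-ranked features with catalog-resolved
#' human-readable descriptions, in rank order (score ties break by
#' lexicographic feature name, fixed at [globalize()] time).
#'
#' @param global A [GlobalImportance-class].
#' @param catalog A [FeatureCatalog-class] (default passthrough).
#' @param k number of features, between 1 and d (default 3).
#' @return data.frame with columns feature, description, direction, score.
#' @export
topFeatures <- function(global, catalog = featureCatalog(), k = 3L) {
  stopifnot(is(global, "GlobalImportance"))
  d <- nrow(global@table)
  if (k < 1L || k > d) stop("k must be between 1 and ", d)
  tb <- utils::head(importanceTable(global), k)
  data.frame(feature = tb$feature,
             description = humanizeFeatures(tb$feature, catalog),
             direction = tb$direction, score = tb$score,
             stringsAsFactors = FALSE)
}

#' Export the global importance bar chart
#'
#' Horizontal bars of the top features (by rank), coloured by direction
#' call.
#'
#' @param global A [GlobalImportance-class].
#' @param path output PNG path.
#' @param k number of features shown (default all, capped at 20).
#' @return `path`, invisibly.
#' @export
exportImportancePlot <- function(global, path, k = NULL) {
  stopifnot(is(global, "GlobalImportance"))
  tb <- importanceTable(global)
  if (!nrow(tb)) stop("empty importance table")
  k <- min(k %||% 20L, nrow(tb))
  tb <- utils::head(tb, k)
  tb$feature <- factor(tb$feature, levels = rev(tb$feature))
  p <- ggplot2::ggplot(tb, ggplot2::aes(x = score, y = feature,
                                        fill = direction)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(positive = "#aa3377",
                                          negative = "#4477aa",
                                          unclear = "grey60")) +
    ggplot2::labs(x = sprintf("global importance (%s)", global@method),
                  y = NULL) +
    ggplot2::theme_minimal()
  ggplot2::ggsave(path, p, width = 6, height = 0.5 + 0.3 * k, dpi = 120,
                  limitsize = FALSE)
  invisible(path)
}
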