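#' @include AllClasses.R
NULL

# Hardcoded surrogate hyperparameters (auditable via the run log). Chosen
# for non-expert usability: no tuning, deterministic single-thread exact
# tree construction.
.surrogateParams <- function(taskKind) {
  list(objective = if (taskKind == "classification") "binary:logistic"
                   else "reg:squarederror",
       max_depth = 6L, eta = 0.3, min_child_weight = 1,
       subsample = 1, colsample_bytree = 1, lambda = 1,
       base_score = 0.5, tree_method = "exact", nthread = 1L)
}
.surrogateNrounds <- 100L

#' Fit the gradient-boosted-tree surrogate model
#'
#' Trains an XGBoost tree ensemble mapping features to the target property
#' and evaluates it on a held-out fraction of the data. Hyperparameters are
#' hardcoded (exposed read-only in the returned model) and training is
#' single-threaded with exact tree construction, so refitting with the same
#' table and seed reproduces the model and its metrics bit-identically.
#'
#' The holdout is a seeded 20% random split, stratified by class for
#' classification. Metrics are computed on the holdout only: RMSE and
#' R-squared for regression, accuracy and F1 (positive class = 1, threshold
#' 0.5) for classification.
#'
#' @param table A [MoleculeTable-class] with at least 10 rows.
#' @param splitSeed integer seed controlling the train/holdout split.
#' @param holdoutFraction fraction held out for evaluation (default 0.2).
#' @return A list with elements `model` ([SurrogateModel-class]) and
#'   `report` ([EvalReport-class]).
#' @export
#' @examples
#' tab <- generateSynthetic(syntheticSpec(n = 200, d = 5, support = c(1, 3),
#'                                        weights = c(2, -1.5), seed = 1))
#' fit <- fitSurrogate(tab, splitSeed = 7)
#' fit$report@metrics$r2
fitSurrogate <- function(table, splitSeed = 1L, holdoutFraction = 0.2) {
  stopifnot(is(table, "MoleculeTable"))
  n <- nrow(table@features)
  if (n < 10L) stop("need at least 10 rows to fit the surrogate, got ", n)
  if (table@taskKind == "classification" &&
      length(unique(table@labels)) < 2L)
    stop("classification labels are single-class; nothing to learn")

  splitSeed <- as.integer(splitSeed)
  test_idx <- .with_seed(splitSeed, {
    if (table@taskKind == "classification") {
      unlist(lapply(split(seq_len(n), table@labels), function(ix)
        sample(ix, max(1L, round(holdoutFraction * length(ix))))),
        use.names = FALSE)
    } else {
      sample(n, max(1L, round(holdoutFraction * n)))
    }
  })
  train_idx <- setdiff(seq_len(n), test_idx)

  params <- .surrogateParams(table@taskKind)
  dtrain <- xgboost::xgb.DMatrix(
    table@features[train_idx, , drop = FALSE],
    label = table@labels[train_idx], nthread = 1)
  booster <- xgboost::xgb.train(params = params, data = dtrain,
                                nrounds = .surrogateNrounds, verbose = 0)

  model <- new("SurrogateModel", booster = booster,
               taskKind = table@taskKind,
               featureNames = colnames(table@features),
               splitSeed = splitSeed,
               hyperparameters = c(params, nrounds = .surrogateNrounds),
               trainIds = table@rowIds[train_idx],
               testIds = table@rowIds[test_idx])

  truth <- table@labels[test_idx]
  pred <- predict(model, table@features[test_idx, , drop = FALSE])
  metrics <- if (table@taskKind == "regression") {
    rmse <- sqrt(mean((pred - truth)^2))
    r2 <- 1 - sum((pred - truth)^2) / sum((truth - mean(truth))^2)
    list(rmse = rmse, r2 = r2)
  } else {
    cls <- as.numeric(pred >= 0.5)
    tp <- sum(cls == 1 & truth == 1)
    prec <- if (sum(cls == 1) > 0) tp / sum(cls == 1) else 0
    rec <- if (sum(truth == 1) > 0) tp / sum(truth == 1) else 0
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    list(accuracy = mean(cls == truth), f1 = f1)
  }
  report <- new("EvalReport", taskKind = table@taskKind, metrics = metrics,
                truth = truth, predicted = pred,
                trainSize = length(train_idx), testSize = length(test_idx))
  list(model = model, report = report)
}

#' Predict from a fitted surrogate model
#'
#' Columns are matched by name: `newdata` may present the model's features
#' in any order, but unknown or missing columns are an error naming the
#' offending columns. Regression returns real values; classification
#' returns the probability of class 1 unless `type = "margin"` requests
#' the additive log-odds margin (the attribution space).
#'
#' @param object A [SurrogateModel-class].
#' @param newdata numeric matrix with named columns.
#' @param type `"response"` (default) or `"margin"`.
#' @return numeric prediction vector.
#' @export
setMethod("predict", "SurrogateModel",
          function(object, newdata, type = c("response", "margin")) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  nm <- colnames(newdata)
  if (is.null(nm)) stop("newdata must have column names")
  unknown <- setdiff(nm, object@featureNames)
  if (length(unknown))
    stop("unknown column(s): ", paste(unknown, collapse = ", "))
  missing <- setdiff(object@featureNames, nm)
  if (length(missing))
    stop("missing column(s): ", paste(missing, collapse = ", "))
  newdata <- newdata[, object@featureNames, drop = FALSE]
  dm <- xgboost::xgb.DMatrix(newdata, nthread = 1)
  stats::predict(object@booster, dm, outputmargin = (type == "margin"))
})

setMethod("show", "SurrogateModel", function(object) {
  cat(sprintf("SurrogateModel (xgboost, %s): %d features, split seed %d\n",
              object@taskKind, length(object@featureNames), object@splitSeed))
  cat(sprintf("  train/test: %d/%d rows\n",
              length(object@trainIds), length(object@testIds)))
})

setMethod("show", "EvalReport", function(object) {
  cat(sprintf("EvalReport (%s holdout, %d rows): %s\n", object@taskKind,
              object@testSize,
              paste(names(object@metrics),
                    sprintf("%.4f", unlist(object@metrics)),
                    sep = " = ", collapse = ", ")))
})

#' Export the surrogate evaluation plot
#'
#' Regression: parity scatter of predicted versus true holdout labels with
#' the identity line. Classification: confusion-matrix heatmap at the 0.5
#' threshold.
#'
#' @param report An [EvalReport-class] with a nonempty holdout.
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
exportEvalPlot <- function(report, path) {
  stopifnot(is(report, "EvalReport"))
  if (!length(report@truth)) stop("empty evaluation report")
  df <- data.frame(truth = report@truth, predicted = report@predicted)
  p <- if (report@taskKind == "regression") {
    ggplot2::ggplot(df, ggplot2::aes(x = truth, y = predicted)) +
      ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                           colour = "grey50") +
      ggplot2::geom_point(alpha = 0.6) +
      ggplot2::labs(x = "observed", y = "predicted",
                    title = sprintf("Holdout parity (RMSE = %.3g, R² = %.3f)",
                                    report@metrics$rmse, report@metrics$r2)) +
      ggplot2::theme_minimal()
  } else {
    cm <- as.data.frame(table(truth = factor(df$truth, c(0, 1)),
                              predicted = factor(as.numeric(df$predicted >= 0.5),
                                                 c(0, 1))))
    ggplot2::ggplot(cm, ggplot2::aes(x = predicted, y = truth, fill = Freq)) +
      ggplot2::geom_tile() +
      ggplot2::geom_text(ggplot2::aes(label = Freq), colour = "white") +
      ggplot2::scale_fill_gradient(low = "#4477aa", high = "#aa3377") +
      ggplot2::labs(title = sprintf("Holdout confusion (accuracy = %.3f)",
                                    report@metrics$accuracy)) +
      ggplot2::theme_minimal()
  }
  ggplot2::ggsave(path, p, width = 5, height = 4, dpi = 120)
  invisible(path)
}
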