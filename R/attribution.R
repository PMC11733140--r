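#' @include surrogate.R
NULL

# Flatten an xgboost booster into parallel node arrays for the C++ walker.
.ensembleArrays <- function(model) {
  dt <- xgboost::xgb.model.dt.tree(model = model@booster)
  dt <- as.data.frame(dt)
  id <- dt$ID
  is_leaf <- dt$Feature == "Leaf"
  feat <- match(dt$Feature, model@featureNames) - 1L
  feat[is_leaf] <- -1L
  if (any(is.na(feat) & !is_leaf))
    stop("tree references unknown feature(s)")
  to_idx <- function(ids) {
    out <- match(ids, id) - 1L
    out[is.na(out)] <- -1L
    out
  }
  list(feature = as.integer(feat),
       split = ifelse(is_leaf, 0, dt$Split),
       yes = to_idx(dt$Yes), no = to_idx(dt$No),
       value = ifelse(is_leaf, dt$Gain, 0),
       roots = to_idx(paste0(sort(unique(dt$Tree)), "-0")))
}

.rowsMatrix <- function(rows, model) {
  X <- if (is(rows, "MoleculeTable")) rows@features else as.matrix(rows)
  if (is.null(colnames(X))) stop("rows must have column names")
  missing <- setdiff(model@featureNames, colnames(X))
  if (length(missing))
    stop("missing column(s): ", paste(missing, collapse = ", "))
  X[, model@featureNames, drop = FALSE]
}

#' Local SHAP attributions by exact interventional tree traversal
#'
#' Computes per-row, per-feature Shapley contributions for the surrogate's
#' tree ensemble under the interventional value function: features absent
#' from a coalition are replaced by values from a background sample, and
#' the coalition value is the mean model output over the background. The
#' per-leaf closed form is exact, so local accuracy holds to floating-point
#' precision: `baseValues[i] + sum(values[i, ])` equals the model's margin
#' prediction for every row (for classification the attribution space is
#' the additive log-odds margin, recorded in `metadata$space`).
#'
#' @param model A [SurrogateModel-class].
#' @param rows matrix (named columns) or [MoleculeTable-class] of rows to
#'   attribute.
#' @param background background rows for the interventional expectation;
#'   defaults to a seeded subsample of `rows` capped at `backgroundSize`.
#' @param backgroundSize background cap (default 100).
#' @param rowCap maximum number of rows attributed (default 500, mirroring
#'   the LIME sampling protocol); larger inputs are subsampled uniformly
#'   without replacement under the seed.
#' @param seed seed for the row and background subsamples.
#' @return A [LocalAttribution-class] with `method = "tree_shap"`.
#' @seealso [exactShapley()] for the subset-enumeration oracle.
#' @export
localTreeShap <- function(model, rows, background = NULL,
                          backgroundSize = 100L, rowCap = 500L, seed = 1L) {
  stopifnot(is(model, "SurrogateModel"))
  X <- .rowsMatrix(rows, model)
  Z <- if (is.null(background)) X else .rowsMatrix(background, model)
  ids <- if (is(rows, "MoleculeTable")) rows@rowIds
         else paste0("r", seq_len(nrow(X)))
  .with_seed(seed, {
    if (nrow(X) > rowCap) {
      keep <- sort(sample(nrow(X), rowCap))
      X <- X[keep, , drop = FALSE]
      ids <- ids[keep]
    }
    if (nrow(Z) > backgroundSize)
      Z <- Z[sample(nrow(Z), backgroundSize), , drop = FALSE]
  })
  ens <- .ensembleArrays(model)
  phi <- .treeshap_cpp(ens$feature, ens$split, ens$yes, ens$no, ens$value,
                       ens$roots, X, Z)
  colnames(phi) <- model@featureNames
  base <- mean(predict(model, Z, type = "margin"))
  new("LocalAttribution", values = phi,
      baseValues = rep(base, nrow(X)), method = "tree_shap",
      sampleRowIds = ids,
      metadata = list(space = if (model@taskKind == "classification")
                        "margin" else "raw",
                      backgroundSize = nrow(Z), rowCap = rowCap))
}

#' Exact Shapley values by subset enumeration (test oracle)
#'
#' Brute-force reference implementation of interventional Shapley values:
#' for every coalition \eqn{T} of features, the value \eqn{v(T)} is the
#' mean margin prediction with coalition features fixed to the explained
#' row and the rest taken from the background rows, and
#' \deqn{\phi_j = \sum_{T \subseteq F \setminus \{j\}}
#'   \frac{|T|!\,(d-|T|-1)!}{d!}\,[v(T \cup \{j\}) - v(T)].}
#' Satisfies \eqn{\sum_j \phi_j = v(F) - v(\emptyset)} exactly. Cost is
#' \eqn{2^d} model calls, so `d` is capped at 12.
#'
#' @param model A [SurrogateModel-class].
#' @param row single named numeric row (vector or 1-row matrix).
#' @param background background matrix with named columns.
#' @return named numeric attribution vector of length d.
#' @export
exactShapley <- function(model, row, background) {
  stopifnot(is(model, "SurrogateModel"))
  if (is.null(dim(row))) row <- matrix(row, nrow = 1,
                                       dimnames = list(NULL, names(row)))
  x <- .rowsMatrix(row, model)[1, ]
  Z <- .rowsMatrix(background, model)
  d <- length(x)
  if (d > 12L) stop("exactShapley enumerates 2^d coalitions; d must be <= 12")
  vcache <- numeric(2^d)
  for (mask in 0:(2^d - 1L)) {
    inT <- bitwAnd(mask, bitwShiftL(1L, 0:(d - 1L))) > 0L
    M <- Z
    M[, inT] <- rep(x[inT], each = nrow(Z))
    vcache[mask + 1L] <- mean(predict(model, M, type = "margin"))
  }
  phi <- stats::setNames(numeric(d), names(x))
  for (j in seq_len(d)) {
    jbit <- bitwShiftL(1L, j - 1L)
    for (mask in 0:(2^d - 1L)) {
      if (bitwAnd(mask, jbit) > 0L) next
      tsize <- sum(bitwAnd(mask, bitwShiftL(1L, 0:(d - 1L))) > 0L)
      w <- factorial(tsize) * factorial(d - tsize - 1L) / factorial(d)
      phi[j] <- phi[j] + w * (vcache[bitwOr(mask, jbit) + 1L] -
                              vcache[mask + 1L])
    }
  }
  phi
}

#' Subsample rows for the LIME analysis
#'
#' LIME explains a sample of the dataset for tractability: the default
#' sample size is 500, or the entire dataset if it has fewer rows. Rows are
#' drawn uniformly without replacement, reproducibly under the seed.
#'
#' @param table A [MoleculeTable-class].
#' @param cap maximum number of rows (default 500).
#' @param seed RNG seed.
#' @return A [MoleculeTable-class] with `min(n, cap)` distinct rows.
#' @export
limeSample <- function(table, cap = 500L, seed = 1L) {
  stopifnot(is(table, "MoleculeTable"), cap >= 1L)
  n <- nrow(table@features)
  if (n <= cap) return(table)
  idx <- .with_seed(seed, sort(sample(n, cap)))
  table[idx, ]
}

#' Local LIME attributions by perturb-and-fit
#'
#' For each sampled row, perturbs the features by resampling each column
#' from its empirical marginal (keeping the original value with probability
#' 0.5), queries the surrogate, and fits a weighted ridge regression of the
#' predictions on the standardised perturbed features. The exponential
#' proximity kernel uses width `0.75 * sqrt(d)` on standardised distances.
#' Weights are the per-row local linear surrogate coefficients;
#' deterministic under the seed.
#'
#' @param model A [SurrogateModel-class].
#' @param rows sampled rows (matrix or [MoleculeTable-class]), typically
#'   from [limeSample()].
#' @param seed RNG seed.
#' @param nPerturbations perturbations per row (default 200).
#' @param ridge ridge penalty on the standardised fit (default 1).
#' @return A [LocalAttribution-class] with `method = "lime"`; kernel width
#'   and perturbation count are recorded in `metadata`.
#' @export
localLime <- function(model, rows, seed = 1L, nPerturbations = 200L,
                      ridge = 1) {
  stopifnot(is(model, "SurrogateModel"))
  X <- .rowsMatrix(rows, model)
  n <- nrow(X); d <- ncol(X)
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  sdv[sdv == 0] <- 1
  kw <- 0.75 * sqrt(d)
  W <- matrix(0, n, d, dimnames = list(NULL, colnames(X)))
  b0 <- numeric(n)
  .with_seed(seed, {
    for (i in seq_len(n)) {
      P <- matrix(0, nPerturbations, d, dimnames = list(NULL, colnames(X)))
      for (j in seq_len(d)) {
        keep <- stats::rbinom(nPerturbations, 1L, 0.5) == 1L
        P[, j] <- ifelse(keep, X[i, j],
                         X[sample.int(n, nPerturbations, replace = TRUE), j])
      }
      P[1, ] <- X[i, ]
      yhat <- predict(model, P, type = "response")
      Pstd <- sweep(sweep(P, 2, mu), 2, sdv, "/")
      xstd <- (X[i, ] - mu) / sdv
      dist2 <- rowSums(sweep(Pstd, 2, xstd)^2)
      wts <- exp(-dist2 / kw^2)
      A <- cbind(1, Pstd)
      AtW <- t(A * wts)
      H <- AtW %*% A + diag(c(0, rep(ridge, d)))
      beta <- solve(H, AtW %*% yhat)
      b0[i] <- beta[1]
      W[i, ] <- beta[-1]
    }
  })
  ids <- if (is(rows, "MoleculeTable")) rows@rowIds
         else paste0("r", seq_len(n))
  new("LocalAttribution", values = W, baseValues = b0, method = "lime",
      sampleRowIds = ids,
      metadata = list(space = "response", nPerturbations = nPerturbations,
                      kernelWidth = kw, ridge = ridge))
}
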