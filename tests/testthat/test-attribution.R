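test_that("tree SHAP satisfies local accuracy and matches the exact Shapley oracle", {
  fit <- fix_fit()
  tab <- fix_reg_table()
  X <- features(tab)[1:6, ]
  Z <- features(tab)[21:28, ]
  la <- localTreeShap(fit$model, X, background = Z)

  # efficiency: base + sum(phi) = margin prediction, every row
  pred <- predict(fit$model, X, type = "margin")
  expect_lt(max(abs(la@baseValues + rowSums(la@values) - pred)), 1e-6)

  # oracle equivalence against 2^d subset enumeration, shared background
  for (i in 1:3) {
    ex <- exactShapley(fit$model, X[i, ], Z)
    expect_lt(max(abs(la@values[i, ] - ex)), 1e-6)
  }
})

test_that("oracle equivalence holds for a classification ensemble (margin space)", {
  ctab <- generateSynthetic(syntheticSpec(n = 300, d = 4, support = c(1L, 3L),
                                          weights = c(2.5, -2),
                                          taskKind = "classification",
                                          seed = 14))
  cfit <- fitSurrogate(ctab, splitSeed = 2)
  X <- features(ctab)[1:3, ]
  Z <- features(ctab)[11:20, ]
  la <- localTreeShap(cfit$model, X, background = Z)
  expect_equal(la@metadata$space, "margin")
  pred <- predict(cfit$model, X, type = "margin")
  expect_lt(max(abs(la@baseValues + rowSums(la@values) - pred)), 1e-6)
  ex <- exactShapley(cfit$model, X[2, ], Z)
  expect_lt(max(abs(la@values[2, ] - ex)), 1e-6)
})

test_that("features absent from every tree receive exactly zero attribution", {
  tab <- generateSynthetic(syntheticSpec(n = 300, d = 6, support = 2L,
                                         weights = 2, noiseSd = 0, seed = 6))
  fit <- fitSurrogate(tab, splitSeed = 1)
  used <- unique(xgboost::xgb.model.dt.tree(model = fit$model@booster)$Feature)
  unused <- setdiff(featureNames(tab), used)
  la <- localTreeShap(fit$model, features(tab)[1:50, ],
                      background = features(tab)[51:100, ])
  expect_true(length(unused) > 0)
  expect_true(all(la@values[, unused] == 0))
  gi <- globalize(la)
  expect_true(all(importanceTable(gi)$score[
    importanceTable(gi)$feature %in% unused] == 0))
})

test_that("a constant model attributes nothing", {
  X <- matrix(rbinom(400, 1, 0.5), 100, 4,
              dimnames = list(NULL, paste0("f", 1:4)))
  tab <- MoleculeTable(X, labels = rep(2.5, 100), taskKind = "regression")
  fit <- fitSurrogate(tab, splitSeed = 1)
  la <- localTreeShap(fit$model, X[1:10, ], background = X[11:30, ])
  expect_true(all(abs(la@values) < 1e-8))
  expect_equal(unname(la@baseValues[1] + sum(la@values[1, ])),
               unname(predict(fit$model, X[1, , drop = FALSE],
                              type = "margin")[1]))
})

test_that("exact Shapley enumerations satisfy the efficiency identity", {
  fit <- fix_fit()
  tab <- fix_reg_table()
  Z <- features(tab)[31:38, ]
  for (i in c(2, 9)) {
    x <- features(tab)[i, ]
    phi <- exactShapley(fit$model, x, Z)
    vF <- predict(fit$model, matrix(x, 1, dimnames = list(NULL, names(x))),
                  type = "margin")
    v0 <- mean(predict(fit$model, Z, type = "margin"))
    expect_equal(sum(phi), unname(vF - v0), tolerance = 1e-10)
  }
  wide <- generateSynthetic(syntheticSpec(n = 30, d = 13, support = 1L,
                                          weights = 1, seed = 3))
  wfit <- fitSurrogate(wide, splitSeed = 1)
  expect_error(exactShapley(wfit$model, features(wide)[1, ],
                            features(wide)[2:5, ]), "12")
})

test_that("LIME sampling honours the 500-row cap and the seed", {
  big <- generateSynthetic(syntheticSpec(n = 1200, d = 3, support = 1L,
                                         weights = 1, seed = 2))
  small <- generateSynthetic(syntheticSpec(n = 80, d = 3, support = 1L,
                                           weights = 1, seed = 2))
  expect_equal(nrow(features(limeSample(big, seed = 5))), 500L)
  expect_equal(nrow(features(limeSample(small, seed = 5))), 80L)
  s1 <- limeSample(big, seed = 5); s2 <- limeSample(big, seed = 5)
  expect_identical(rowIds(s1), rowIds(s2))
  expect_false(anyDuplicated(rowIds(s1)) > 0)
  expect_false(identical(rowIds(limeSample(big, seed = 6)), rowIds(s1)))
})

test_that("LIME weights vanish for a constant model and are seed-deterministic", {
  X <- matrix(rbinom(240, 1, 0.5), 60, 4,
              dimnames = list(NULL, paste0("f", 1:4)))
  tab <- MoleculeTable(X, labels = rep(1.5, 60), taskKind = "regression")
  fit <- fitSurrogate(tab, splitSeed = 1)
  ll <- localLime(fit$model, X[1:20, ], seed = 3)
  expect_true(all(abs(ll@values) < 1e-3))

  fit2 <- fix_fit()
  rows <- features(fix_reg_table())[1:15, ]
  a <- localLime(fit2$model, rows, seed = 9)
  b <- localLime(fit2$model, rows, seed = 9)
  expect_identical(a@values, b@values)
  expect_false(identical(localLime(fit2$model, rows, seed = 10)@values,
                         a@values))
})

test_that("LIME recovers a single planted feature across seeds", {
  hits <- vapply(1:20, function(s) {
    tab <- generateSynthetic(syntheticSpec(n = 150, d = 5, support = 3L,
                                           weights = 2, noiseSd = 0,
                                           seed = 200 + s))
    fit <- fitSurrogate(tab, splitSeed = s)
    ll <- localLime(fit$model, features(tab)[1:40, ], seed = s)
    names(which.max(colMeans(abs(ll@values)))) == "f3"
  }, logical(1))
  expect_gte(sum(hits), 19)
})

test_that("globalization matches hand-computed aggregates and direction rules", {
  mk <- function(vals, method = "tree_shap")
    new("LocalAttribution", values = vals,
        baseValues = numeric(nrow(vals)), method = method,
        sampleRowIds = paste0("r", seq_len(nrow(vals))), metadata = list())

  g <- importanceTable(globalize(mk(
    matrix(c(1, 1, 0, 0), 2, 2, dimnames = list(NULL, c("f1", "f2"))))))
  expect_equal(g$score, c(1, 0))
  expect_equal(g$direction, c("positive", "unclear"))

  g2 <- importanceTable(globalize(mk(
    matrix(c(1, -1), 2, 1, dimnames = list(NULL, "f1")))))
  expect_equal(g2$score, 1)
  expect_equal(g2$direction, "unclear")

  # brute-force aggregation oracle on a random matrix
  set.seed(31)
  M <- matrix(rnorm(300), 50, 6, dimnames = list(NULL, paste0("f", 1:6)))
  g3 <- globalize(mk(M))@table
  byhand <- vapply(1:6, function(j) {
    acc <- 0
    for (i in 1:50) acc <- acc + abs(M[i, j])
    acc / 50
  }, numeric(1))
  expect_equal(g3$score, byhand)

  # row-permutation invariance; column permutation equivariance
  gp <- globalize(mk(M[sample(50), ]))@table
  expect_equal(gp$score, g3$score)
  perm <- c(3, 1, 2, 6, 5, 4)
  gq <- globalize(mk(M[, perm]))@table
  expect_equal(gq$score, g3$score[perm])
  expect_equal(gq$rank, g3$rank[perm])

  # LIME z-scores: standardised across features, zero-spread warning
  gl <- globalize(mk(abs(M), method = "lime"))@table
  s <- colMeans(abs(abs(M)))
  expect_equal(gl$zscore, (s - mean(s)) / sd(s), ignore_attr = TRUE)
  expect_equal(gl$score, pmax(gl$zscore, 0))
  flat <- mk(matrix(1, 4, 3, dimnames = list(NULL, c("a", "b", "c"))),
             method = "lime")
  expect_warning(gf <- globalize(flat), "Z-scores")
  expect_true(all(gf@table$zscore == 0))

  expect_error(globalize(mk(matrix(numeric(0), 0, 2,
                                   dimnames = list(NULL, c("a", "b"))))),
               "empty")
})

test_that("top-k selection respects rank, ties and the catalog", {
  mk <- function(vals)
    new("LocalAttribution", values = vals,
        baseValues = numeric(nrow(vals)), method = "tree_shap",
        sampleRowIds = "r1", metadata = list())
  g <- globalize(mk(matrix(c(3, 1, 2), 1, 3,
                           dimnames = list(NULL, c("f1", "f2", "f3")))))
  expect_equal(topFeatures(g, k = 2)$feature, c("f1", "f3"))
  expect_equal(topFeatures(g, k = 3)$feature, c("f1", "f3", "f2"))

  # equal scores: lexicographic feature name breaks the tie
  gt <- globalize(mk(matrix(c(2, 2, 1), 1, 3,
                            dimnames = list(NULL, c("f_b", "f_a", "f_c")))))
  expect_equal(topFeatures(gt, k = 2)$feature, c("f_a", "f_b"))

  cat <- featureCatalog(c(f1 = "presence of a carbonyl group"))
  expect_equal(topFeatures(g, cat, k = 1)$description,
               "presence of a carbonyl group")
  expect_error(topFeatures(g, k = 0), "between")
  expect_error(topFeatures(g, k = 9), "between")
})

test_that("importance plot export writes a file", {
  fit <- fix_fit()
  la <- localTreeShap(fit$model, features(fix_reg_table())[1:30, ])
  png <- withr::local_tempfile(fileext = ".png")
  exportImportancePlot(globalize(la), png)
  expect_gt(file.size(png), 0)
})
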