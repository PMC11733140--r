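mk_expl <- function(dirs, feats = names(dirs)) {
  new("Explanation", runId = paste0("r", sample.int(1e6, 1)),
      text = "synthetic",
      hypotheses = data.frame(feature = feats, description = feats,
                              direction = unname(dirs), supported = TRUE,
                              stringsAsFactors = FALSE),
      citations = data.frame())
}

test_that("hypothesis tallies count directions and treat absences as unclear", {
  ex <- replicate(5, mk_expl(c(f1 = "positive", f2 = "negative")),
                  simplify = FALSE)
  t1 <- tallyHypotheses(ex)
  expect_equal(t1@counts["f1", "positive"], 5L)
  expect_equal(t1@counts["f2", "negative"], 5L)
  expect_true(all(rowSums(t1@counts) == 5L))

  # run 3 omits f2 entirely -> counted unclear for that run
  ex[[3]] <- mk_expl(c(f1 = "positive"))
  t2 <- tallyHypotheses(ex)
  expect_equal(t2@counts["f2", "unclear"], 1L)
  expect_equal(t2@counts["f2", "negative"], 4L)
  expect_true(all(rowSums(t2@counts) == 5L))

  expect_error(tallyHypotheses(list()), "empty")
})

test_that("precision matches the weighted formula on edge cases and random tallies", {
  tally <- function(mat, runs) new("HypothesisTally",
                                   counts = mat, nRuns = as.integer(runs))
  cn <- c("positive", "negative", "unclear")
  m <- function(...) matrix(as.integer(c(...)), ncol = 3, byrow = TRUE,
                            dimnames = list(NULL, cn))

  # all unclear -> 0; single feature fully consistent -> 1
  expect_equal(hypothesisPrecision(tally(m(0, 0, 5), 5))$precision, 0)
  expect_equal(hypothesisPrecision(tally(m(5, 0, 0), 5))$precision, 1)
  # two features, five runs: (|3-2| + |5-0|) / 10 = 0.6
  expect_equal(hypothesisPrecision(tally(m(3, 2, 0, 5, 0, 0), 5))$precision,
               0.6)

  # 50 random tallies against the independent loop oracle; bounded in [0,1]
  set.seed(99)
  for (i in 1:50) {
    nf <- sample(1:6, 1); nr <- sample(1:8, 1)
    cts <- t(vapply(seq_len(nf), function(...) {
      as.integer(stats::rmultinom(1, nr, runif(3)))
    }, integer(3)))
    colnames(cts) <- cn
    p <- hypothesisPrecision(tally(cts, nr))$precision
    expect_equal(p, oracle_precision(cts, nr))
    expect_gte(p, 0); expect_lte(p, 1)

    # invariance under permutation of features
    expect_equal(hypothesisPrecision(tally(cts[sample(nf), , drop = FALSE],
                                           nr))$precision, p)
  }

  # converting positives to unclear never increases precision when n_neg = 0
  cts <- m(4, 0, 1, 3, 0, 2)
  p_prev <- hypothesisPrecision(tally(cts, 5))$precision
  for (step in 1:4) {
    cts[1, "positive"] <- cts[1, "positive"] - 1L
    cts[1, "unclear"] <- cts[1, "unclear"] + 1L
    p_now <- hypothesisPrecision(tally(cts, 5))$precision
    expect_lte(p_now, p_prev)
    p_prev <- p_now
  }

  # malformed tallies are rejected by the class invariant
  expect_error(tally(m(3, 3, 3), 5), "sum to nRuns")
})

test_that("LCS equals the recursive oracle and handles identities", {
  expect_equal(lcsLength("a b c", "a c"), 2L)
  x <- "the cat sat on the mat"
  expect_equal(lcsLength(x, x), 6L)
  expect_equal(lcsLength("", "a b"), 0L)

  set.seed(17)
  vocab <- letters[1:4]
  for (i in 1:25) {
    a <- sample(vocab, sample(0:10, 1), replace = TRUE)
    b <- sample(vocab, sample(0:10, 1), replace = TRUE)
    expect_equal(lcsLength(a, b), oracle_lcs(a, b))
  }
})

test_that("ROUGE-L follows the F1 convention", {
  expect_equal(unname(rougeL("same words here", "same words here")["f"]), 1)
  expect_equal(unname(rougeL("aa bb cc", "dd ee ff")["f"]), 0)
  expect_equal(unname(rougeL("", "something")), c(0, 0, 0))

  # hand DP: candidate "the cat sat", reference "the cat ran" -> LCS 2
  sc <- rougeL("the cat sat", "the cat ran")
  expect_equal(unname(sc["recall"]), 2 / 3)
  expect_equal(unname(sc["precision"]), 2 / 3)
  expect_equal(unname(sc["f"]), 2 / 3)

  # symmetry of F under argument swap
  set.seed(5)
  for (i in 1:10) {
    a <- paste(sample(letters[1:6], 8, TRUE), collapse = " ")
    b <- paste(sample(letters[1:6], 11, TRUE), collapse = " ")
    expect_equal(rougeL(a, b)["f"], rougeL(b, a)["f"], ignore_attr = TRUE)
  }
})

test_that("ROUGE variability aggregates all unordered pairs", {
  same <- replicate(5, "identical text for every run", simplify = FALSE)
  rv <- rougeVariability(same)
  expect_equal(rv$mean, 1)
  expect_equal(rv$sd, 0)
  expect_equal(nrow(rv$pairs), 10L)

  expect_equal(nrow(rougeVariability(list("a b", "a c"))$pairs), 1L)
  expect_error(rougeVariability(list("only one")), "at least 2")

  # mean equals a direct loop over pairs
  set.seed(23)
  texts <- replicate(5, paste(sample(letters[1:8], 12, TRUE), collapse = " "))
  rv2 <- rougeVariability(as.list(texts))
  acc <- c()
  for (i in 1:4) for (j in (i + 1):5)
    acc <- c(acc, unname(rougeL(texts[i], texts[j])["f"]))
  expect_equal(rv2$mean, mean(acc))
  expect_equal(rv2$sd, sd(acc))
})

test_that("the citation audit verifies resolution and substring support", {
  idx <- fix_index()
  top <- data.frame(feature = c("f1", "f4"), description = c("f1", "f4"),
                    direction = c("positive", "negative"),
                    score = c(1, 0.5), stringsAsFactors = FALSE)
  rets <- lapply(top$description, retrieveForFeature,
                 property = "aqueous solubility", index = idx)
  names(rets) <- top$feature
  b <- assemblePrompt(top, rets, "aqueous solubility")
  ex <- lapply(generateExplanations(mockBackend(), b, nRuns = 3,
                                    baseSeed = 11),
               attachCitations, index = idx)
  audit <- auditCitations(ex, idx)
  expect_gt(audit$total, 0)
  # mock cites only provided excerpts: everything resolved and supported
  expect_true(all(audit$citations$resolved))
  expect_true(all(audit$citations$supported))
  expect_equal(audit$correct, audit$total)
  expect_equal(audit$accuracy, 1)
  expect_equal(audit$perExplanation, 1)

  # a citation to an unregistered document is unresolved
  fake <- ex[[1]]
  fake@citations <- data.frame(key = "(Ghost, 1999)", doc_id = "doc_404",
                               chunk_index = 0L, feature = "f1",
                               resolved = FALSE, stringsAsFactors = FALSE)
  a2 <- auditCitations(list(fake), idx)
  expect_false(any(a2$citations$resolved))

  # a resolvable chunk that never mentions the feature is unsupported
  distr <- idx@chunks[grep("spectrometer", idx@chunks$text)[1], ]
  fake@citations <- data.frame(key = "(X, 2020)", doc_id = distr$doc_id,
                               chunk_index = distr$chunk_index,
                               feature = "f1", resolved = TRUE,
                               stringsAsFactors = FALSE)
  a3 <- auditCitations(list(fake), idx)
  expect_true(all(a3$citations$resolved))
  expect_false(any(a3$citations$supported))
})
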