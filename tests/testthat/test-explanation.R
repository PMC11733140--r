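fix_bundle <- function(k = 3) {
  idx <- fix_index()
  top <- data.frame(
    feature = c("f1", "f4", "f2")[seq_len(k)],
    description = c("f1", "f4", "f2")[seq_len(k)],
    direction = c("positive", "negative", "unclear")[seq_len(k)],
    score = c(1, 0.8, 0.1)[seq_len(k)], stringsAsFactors = FALSE)
  rets <- lapply(seq_len(k), function(i)
    retrieveForFeature(top$description[i], "aqueous solubility", idx))
  names(rets) <- top$feature
  assemblePrompt(top, rets, "aqueous solubility")
}

test_that("prompt assembly is deterministic with one tagged block per feature", {
  b <- fix_bundle()
  txt <- promptText(b)
  expect_identical(txt, promptText(fix_bundle()))
  expect_equal(length(b@blocks), 3L)
  expect_equal(length(gregexpr("## FEATURE", txt)[[1]]), 3L)
  # every excerpt carries a resolvable source tag
  ev <- regmatches(txt, gregexpr("\\[E[0-9]+ doc=doc_[0-9]+ chunk=[0-9]+\\]",
                                 txt))[[1]]
  expect_gte(length(ev), 3L)
  expect_match(txt, "TEMPLATE: cx-template-1")
  expect_match(txt, "was not found in the given documents")

  # a feature with no retrievals gets an explicit empty-evidence marker
  top <- data.frame(feature = "f9", description = "f9",
                    direction = "unclear", score = 0,
                    stringsAsFactors = FALSE)
  b2 <- assemblePrompt(top, list(), "aqueous solubility")
  expect_match(promptText(b2), "NO_EVIDENCE")
})

test_that("the mock backend is deterministic and reads direction from evidence", {
  b <- fix_bundle()
  backend <- mockBackend()
  prompt <- promptText(b)
  expect_identical(generate(backend, prompt, 5L), generate(backend, prompt, 5L))
  expect_false(identical(generate(backend, prompt, 5L),
                         generate(backend, prompt, 6L)))

  ex <- generateExplanations(backend, b, nRuns = 5, baseSeed = 40)
  expect_length(ex, 5L)
  # equal seeds => byte-identical runs
  ex2 <- generateExplanations(backend, b, nRuns = 5, baseSeed = 40)
  expect_identical(vapply(ex, slot, character(1), "text"),
                   vapply(ex2, slot, character(1), "text"))

  # the corpus asserts f1 increases / f4 decreases the property
  hyp <- ex[[1]]@hypotheses
  expect_equal(hyp$direction[hyp$feature == "f1"], "positive")
  expect_equal(hyp$direction[hyp$feature == "f4"], "negative")
  expect_true(all(hyp$supported[hyp$feature %in% c("f1", "f4")]))
  expect_match(ex[[1]]@text, "\\[CITE doc=doc_[0-9]+ chunk=[0-9]+\\]")
})

test_that("features without evidence carry the verbatim disclaimer", {
  top <- data.frame(feature = "f9", description = "f9",
                    direction = "unclear", score = 0,
                    stringsAsFactors = FALSE)
  b <- assemblePrompt(top, list(), "aqueous solubility")
  ex <- generateExplanations(mockBackend(), b, nRuns = 2, baseSeed = 1)
  for (e in ex) {
    expect_match(e@text, "an explicit relationship was not found in the given documents",
                 fixed = TRUE)
    expect_equal(e@hypotheses$direction, "unclear")
    expect_false(any(e@hypotheses$supported))
  }
})

test_that("citations resolve against the registry and ghosts are flagged", {
  idx <- fix_index()
  b <- fix_bundle()
  ex <- generateExplanations(mockBackend(), b, nRuns = 1, baseSeed = 2)[[1]]
  res <- attachCitations(ex, idx)
  expect_gte(nrow(res@citations), 2L)
  expect_true(all(res@citations$resolved))
  expect_true(all(res@citations$doc_id %in% idx@documents$doc_id))
  expect_false(grepl("[CITE", res@text, fixed = TRUE))
  expect_match(res@text, "\\([A-Z][a-z]+, 20[0-9]{2}\\)")

  # unknown structured marker and free-text ghost citation
  ghost <- new("Explanation", runId = "g", text = paste(
    "FEATURE: f1\nDIRECTION: positive\nHYPOTHESIS: claim",
    "[CITE doc=doc_999 chunk=0] and see Ghost et al. 1999."),
    hypotheses = data.frame(), citations = data.frame())
  gres <- attachCitations(ghost, idx)
  expect_match(gres@text, "[unresolved]", fixed = TRUE)
  expect_false(any(gres@citations$resolved))
  expect_false(grepl("Ghost et al. 1999", gres@text, fixed = TRUE))

  # zero markers: text unchanged, zero citations
  plain <- new("Explanation", runId = "p", text = "No citations here.",
               hypotheses = data.frame(), citations = data.frame())
  pres <- attachCitations(plain, idx)
  expect_identical(pres@text, "No citations here.")
  expect_equal(nrow(pres@citations), 0L)
})

test_that("the markdown report renders deterministically with all sections", {
  fit <- fix_fit()
  la <- localTreeShap(fit$model, features(fix_reg_table())[1:30, ])
  gi <- globalize(la)
  idx <- fix_index()
  b <- fix_bundle()
  ex <- lapply(generateExplanations(mockBackend(), b, nRuns = 2,
                                    baseSeed = 3),
               attachCitations, index = idx)
  f1 <- withr::local_tempfile(fileext = ".md")
  f2 <- withr::local_tempfile(fileext = ".md")
  renderReport(ex, gi, fit$report, idx, f1)
  renderReport(ex, gi, fit$report, idx, f2)
  expect_identical(readLines(f1), readLines(f2))
  md <- paste(readLines(f1), collapse = "\n")
  for (sec in c("## Surrogate model", "## Ranked features",
                "## Generated explanations", "## References"))
    expect_match(md, sec, fixed = TRUE)
})
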