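test_that("corpus ingestion reads text verbatim with stable ids", {
  d <- withr::local_tempdir()
  writeLines(c("Alpha study (2019)", "", "body text one"),
             file.path(d, "a.txt"))
  writeLines("Beta notes", file.path(d, "b.md"))
  docs <- ingestCorpus(d)
  expect_equal(nrow(docs), 2L)
  expect_equal(docs$text[docs$source == "a.txt"],
               "Alpha study (2019)\n\nbody text one")
  expect_equal(docs$title[docs$source == "a.txt"], "Alpha study (2019)")
  expect_identical(ingestCorpus(d)$doc_id, docs$doc_id)

  # changing content changes the id
  writeLines("Alpha study (2019) revised", file.path(d, "a.txt"))
  expect_false(ingestCorpus(d)$doc_id[1] == docs$doc_id[1])

  empty <- withr::local_tempdir()
  expect_error(ingestCorpus(empty), "empty corpus")
  expect_error(ingestCorpus(file.path(empty, "nope")), "not found")
})

test_that("chunking follows the window arithmetic and reconstructs the text", {
  cfg <- retrievalConfig(chunkSize = 1000L, chunkOverlap = 200L)

  short <- chunkDocument(strrep("x", 10), cfg)
  expect_equal(nrow(short), 1L)
  expect_equal(short$text, strrep("x", 10))

  # 2500 chars, size 1000, overlap 200: windows at 1, 801, 1601, 2401
  txt <- strrep("a", 2500)
  ch <- chunkDocument(txt, cfg)
  expect_equal(nrow(ch), 4L)
  expect_equal(ch$start, c(1L, 801L, 1601L, 2401L))
  expect_equal(ch$end, c(1001L, 1801L, 2501L, 2501L))
  expect_equal(ch$chunk_index, 0:3)

  expect_error(retrievalConfig(chunkSize = 100L, chunkOverlap = 100L),
               "smaller")

  # reconstruction: concatenating the de-overlapped chunks restores the
  # document byte-exactly, including when whitespace cuts shift the ends
  set.seed(12)
  for (rep in 1:5) {
    words <- paste(sample(c("lorem", "ipsum", "dolor", "sit", "amet",
                            "consectetur"), 700, replace = TRUE),
                   collapse = " ")
    cc <- chunkDocument(words, retrievalConfig(chunkSize = 300L,
                                               chunkOverlap = 60L))
    covered <- 0L
    rebuilt <- ""
    for (i in seq_len(nrow(cc))) {
      from <- covered - cc$start[i] + 2L  # 1-based offset into chunk text
      if (from <= nchar(cc$text[i]))
        rebuilt <- paste0(rebuilt, substring(cc$text[i], max(1L, from)))
      covered <- max(covered, cc$end[i] - 1L)
    }
    expect_identical(rebuilt, words)
    # spans lie within the document
    expect_true(all(cc$start >= 1 & cc$end <= nchar(words) + 1))
  }
})

test_that("the hashed TF-IDF embedder is deterministic with cosine structure", {
  v1 <- embedTexts(c("the quick brown fox", "the quick brown fox"))
  expect_identical(v1[1, ], v1[2, ])
  expect_equal(sum(v1[1, ] * v1[2, ]), 1.0, tolerance = 1e-12)
  expect_identical(embedTexts("abc"), embedTexts("abc"))

  # disjoint vocabularies: near-orthogonal (hash collisions bounded)
  v2 <- embedTexts(c("alpha beta gamma delta", "epsilon zeta eta theta"))
  expect_lt(abs(sum(v2[1, ] * v2[2, ])), 0.05)

  expect_warning(z <- embedTexts(c("words here", "")), "zero-length")
  expect_true(all(z[2, ] == 0))
  expect_error(embedTexts(character(0)), "nonempty")
})

test_that("MMR selection equals similarity sort at lambda 1 and the greedy oracle otherwise", {
  set.seed(77)
  for (rep in 1:10) {
    n <- sample(4:8, 1)
    C <- matrix(rnorm(n * 6), n, 6)
    q <- rnorm(6)
    sims <- apply(C, 1, function(r) sum(r * q) / sqrt(sum(r^2) * sum(q^2)))
    expect_equal(mmrSelect(q, C, lambda = 1, k = n), order(sims, decreasing = TRUE))
    k <- sample(1:n, 1)
    expect_equal(mmrSelect(q, C, lambda = 0.5, k = k),
                 oracle_mmr(q, C, 0.5, k))
    expect_equal(mmrSelect(q, C, lambda = 0.2, k = k),
                 oracle_mmr(q, C, 0.2, k))
  }

  # k = 1 returns the single most similar candidate; k > n returns all, distinct
  C <- matrix(rnorm(30), 5, 6)
  q <- rnorm(6)
  sims <- apply(C, 1, function(r) sum(r * q) / sqrt(sum(r^2) * sum(q^2)))
  expect_equal(mmrSelect(q, C, 0.5, 1), which.max(sims))
  sel <- mmrSelect(q, C, 0.5, 50)
  expect_equal(sort(sel), 1:5)

  # exact ties break toward the lowest index
  Cd <- rbind(c(1, 0), c(1, 0), c(0, 1))
  expect_equal(mmrSelect(c(1, 0), Cd, 1, 2)[1], 1L)
})

test_that("feature-query retrieval surfaces the asserting document first", {
  idx <- fix_index()
  rr <- retrieveForFeature("f1", "aqueous solubility", idx)
  expect_s4_class(rr, "RetrievalResult")
  expect_false(rr@lowConfidence)
  top_doc <- idx@documents$source[idx@documents$doc_id == rr@chunks$doc_id[1]]
  expect_equal(top_doc, "study_01.txt")
  expect_true(grepl("f1", rr@chunks$text[1]))

  # out-of-vocabulary query: flagged low confidence
  rr2 <- retrieveForFeature("zqxzqx", "wvwvwv", idx)
  expect_true(rr2@lowConfidence)

  # kRetrieve larger than the chunk count returns every chunk
  docs <- ingestCorpus(fix_corpus_dir())
  tiny <- indexCorpus(docs, retrievalConfig(chunkSize = 5000L,
                                            chunkOverlap = 100L,
                                            kRetrieve = 50L))
  rr3 <- retrieveForFeature("f1", "aqueous solubility", tiny)
  expect_equal(nrow(rr3@chunks), nrow(tiny@chunks))
})
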