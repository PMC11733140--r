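# Shared fixtures, built in code at load time. Kept deliberately small so
# the full suite stays fast; heavier scenarios construct their own data.

# A regression table with two planted features and mild noise.
fix_reg_table <- function(seed = 11L, n = 300L) {
  generateSynthetic(syntheticSpec(n = n, d = 6, support = c(1L, 4L),
                                  weights = c(1.5, -1.5), noiseSd = 0.1,
                                  taskKind = "regression", seed = seed))
}

# A small fitted surrogate reused across attribution tests.
fix_fit <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- fitSurrogate(fix_reg_table(), splitSeed = 7L)
    cache
  }
})

# Toy corpus asserting f1 up / f4 down for a named property.
fix_corpus_dir <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      d <- file.path(tempdir(), "cx-fix-corpus")
      syntheticCorpus(c("f1", "f4"), c("positive", "negative"),
                      "aqueous solubility", d, nDistractors = 2, seed = 3L)
      cache <<- d
    }
    cache
  }
})

fix_index <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- indexCorpus(ingestCorpus(fix_corpus_dir()),
                            retrievalConfig(chunkSize = 400L,
                                            chunkOverlap = 80L))
    cache
  }
})

# Independent brute-force greedy MMR, evaluated step by step (test oracle).
oracle_mmr <- function(q, C, lambda, k) {
  cosv <- function(a, b) {
    na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
    if (na == 0 || nb == 0) 0 else sum(a * b) / (na * nb)
  }
  simq <- apply(C, 1, cosv, b = q)
  sel <- integer(0)
  rem <- seq_len(nrow(C))
  for (s in seq_len(min(k, nrow(C)))) {
    best <- NA_integer_; bestv <- -Inf
    for (ci in rem) {
      v <- if (!length(sel)) simq[ci] else {
        red <- -Inf
        for (si in sel) red <- max(red, cosv(C[ci, ], C[si, ]))
        lambda * simq[ci] - (1 - lambda) * red
      }
      if (v > bestv + 1e-12) { bestv <- v; best <- ci }
    }
    sel <- c(sel, best)
    rem <- setdiff(rem, best)
  }
  sel
}

# Exponential-time recursive LCS (test oracle for short sequences).
oracle_lcs <- function(a, b) {
  if (!length(a) || !length(b)) return(0L)
  if (a[1] == b[1]) return(1L + oracle_lcs(a[-1], b[-1]))
  max(oracle_lcs(a[-1], b), oracle_lcs(a, b[-1]))
}

# Direct loop evaluation of the hypothesis-precision formula (test oracle).
oracle_precision <- function(counts, nRuns) {
  acc <- 0
  for (i in seq_len(nrow(counts)))
    acc <- acc + abs(1 * counts[i, "positive"] +
                     (-1) * counts[i, "negative"] +
                     0 * counts[i, "unclear"])
  unname(acc / (nrow(counts) * nRuns))
}
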