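# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministic polynomial rolling hash of a character string.
# Returns a non-negative integer-valued double < mod. Used for stable
# document ids and for the hashing-trick term embedder; NOT cryptographic.
.strhash <- function(x, mod = 2147483647) {
  bytes <- as.integer(charToRaw(enc2utf8(x)))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% mod
  h
}

# Memoising wrapper for token hashing (tokens recur heavily in a corpus).
.token_hasher <- function(dim) {
  cache <- new.env(parent = emptyenv())
  function(tok) {
    v <- cache[[tok]]
    if (is.null(v)) {
      v <- as.integer(.strhash(tok) %% dim) + 1L
      cache[[tok]] <- v
    }
    v
  }
}

# Run code with a temporary RNG seed, restoring the caller's RNG state.
.with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

# Fan a master seed out to named per-stage seeds, all < 2^31.
.fan_seed <- function(seed, stages) {
  seed <- as.integer(seed)
  out <- vapply(seq_along(stages),
                function(i) (abs(seed) * 101L + i * 7919L) %% 2147483629L,
                integer(1))
  names(out) <- stages
  out
}

.assert <- function(ok, msg) if (!isTRUE(ok)) stop(msg, call. = FALSE)

# Structured one-line log records (stderr); quiet by default in tests.
.log <- function(..., verbose = getOption("chemxplain.verbose", FALSE)) {
  if (isTRUE(verbose)) message("[chemxplain] ", ...)
  invisible(NULL)
}

# Whitespace tokenizer used by ROUGE-L (verbatim tokens, no normalisation).
.ws_tokens <- function(x) {
  toks <- strsplit(trimws(x), "\\s+")[[1]]
  toks[nzchar(toks)]
}

# Lowercased alphanumeric tokens used by the TF-IDF embedder.
.text_tokens <- function(x) {
  toks <- strsplit(tolower(x), "[^a-z0-9]+")[[1]]
  toks[nzchar(toks)]
}
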