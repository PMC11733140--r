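#' @include AllClasses.R
NULL

#' Retrieval configuration
#'
#' Defaults: 1000-character chunks with 200-character overlap, MMR
#' trade-off lambda = 0.5, 4 excerpts per query, 512-dimensional hashed
#' TF-IDF embeddings.
#'
#' @param chunkSize chunk window in characters.
#' @param chunkOverlap overlap between consecutive chunks (< chunkSize).
#' @param lambda MMR relevance-diversity trade-off in \[0, 1\].
#' @param kRetrieve excerpts per query.
#' @param embedDim embedding dimensionality.
#' @param embedder embedder tag (only `"hashed_tfidf"` is built in).
#' @return A [RetrievalConfig-class].
#' @export
retrievalConfig <- function(chunkSize = 1000L, chunkOverlap = 200L,
                            lambda = 0.5, kRetrieve = 4L, embedDim = 512L,
                            embedder = "hashed_tfidf") {
  new("RetrievalConfig", chunkSize = as.integer(chunkSize),
      chunkOverlap = as.integer(chunkOverlap), lambda = as.numeric(lambda),
      kRetrieve = as.integer(kRetrieve), embedDim = as.integer(embedDim),
      embedder = embedder)
}

#' Ingest a literature corpus from a directory
#'
#' Reads `.txt` and `.md` files verbatim (UTF-8). PDF files are skipped
#' with a warning (no text extractor is bundled); empty extractions are
#' logged and skipped. Document ids are stable hashes of filename plus
#' content, so re-ingesting an unchanged directory reproduces identical
#' ids. The title is taken best-effort from the first non-empty line.
#'
#' @param dir corpus directory.
#' @return data.frame with columns doc_id, source, title, text, nchar.
#' @export
ingestCorpus <- function(dir) {
  if (!dir.exists(dir)) stop("corpus directory not found: ", dir)
  files <- sort(list.files(dir, full.names = TRUE))
  docs <- list()
  for (f in files) {
    ext <- tolower(tools::file_ext(f))
    if (ext == "pdf") {
      warning("skipping PDF (no text extractor bundled): ", basename(f))
      next
    }
    if (!ext %in% c("txt", "md")) next
    txt <- tryCatch(paste(readLines(f, warn = FALSE, encoding = "UTF-8"),
                          collapse = "\n"),
                    error = function(e) {
                      warning("unreadable file skipped: ", basename(f))
                      NULL
                    })
    if (is.null(txt)) next
    if (!nzchar(trimws(txt))) {
      .log("empty extraction skipped: ", basename(f))
      next
    }
    lines <- strsplit(txt, "\n")[[1]]
    title <- trimws(lines[nzchar(trimws(lines))][1])
    docs[[length(docs) + 1L]] <- data.frame(
      doc_id = sprintf("doc_%d", .strhash(paste0(basename(f), "\x01", txt))),
      source = basename(f), title = title, text = txt,
      nchar = nchar(txt), stringsAsFactors = FALSE)
  }
  if (!length(docs)) stop("empty corpus: no readable documents in ", dir)
  do.call(rbind, docs)
}

#' Split a document into overlapping character-span chunks
#'
#' Sliding window of `chunkSize` characters advancing by
#' `chunkSize - chunkOverlap`, preferring to cut at whitespace when a space
#' occurs within 50 characters before the nominal cut. Spans are
#' half-open `[start, end)`; stripping the overlaps and concatenating
#' reconstructs the document text exactly.
#'
#' @param text document text (single string).
#' @param cfg A [RetrievalConfig-class].
#' @param doc_id id recorded on each chunk.
#' @return data.frame: doc_id, chunk_index, text, start, end.
#' @export
chunkDocument <- function(text, cfg = retrievalConfig(), doc_id = "doc") {
  stopifnot(is(cfg, "RetrievalConfig"))
  validObject(cfg)
  nc <- nchar(text)
  size <- cfg@chunkSize; ov <- cfg@chunkOverlap
  stride <- size - ov
  starts <- seq.int(1L, max(nc, 1L), by = stride)
  ends <- integer(length(starts))
  for (i in seq_along(starts)) {
    start <- starts[i]
    end <- min(start + size - 1L, nc)
    if (end < nc) {
      # prefer a whitespace cut within 50 chars before the nominal end,
      # provided the shortened chunk still reaches the next window's start
      # (no coverage gap)
      tail_seg <- substr(text, max(start, end - 49L), end)
      ws <- gregexpr("[ \t\n]", tail_seg)[[1]]
      if (ws[1] != -1L) {
        cand <- max(start, end - 49L) + max(ws) - 1L
        if (cand >= start + stride - 1L) end <- cand
      }
    }
    ends[i] <- end
  }
  data.frame(doc_id = doc_id, chunk_index = seq_along(starts) - 1L,
             text = substring(text, starts, ends),
             start = starts, end = ends + 1L,  # half-open [start, end)
             stringsAsFactors = FALSE)
}

# Hashed term-frequency embedding; idf-weighted and L2-normalised.
.embed_matrix <- function(texts, dim, idf = NULL) {
  hasher <- .token_hasher(dim)
  tf <- matrix(0, length(texts), dim)
  for (i in seq_along(texts)) {
    toks <- .text_tokens(texts[i])
    if (!length(toks)) {
      warning("zero-length text at position ", i, "; zero vector emitted")
      next
    }
    idx <- vapply(toks, hasher, integer(1))
    cnt <- table(idx)
    tf[i, as.integer(names(cnt))] <- as.numeric(cnt)
  }
  if (is.null(idf)) {
    df <- colSums(tf > 0)
    idf <- log((1 + length(texts)) / (1 + df)) + 1
  }
  V <- sweep(tf, 2, idf, "*")
  nrm <- sqrt(rowSums(V^2))
  nrm[nrm == 0] <- 1
  list(vectors = V / nrm, idf = idf)
}

#' Embed texts with the offline hashed TF-IDF embedder
#'
#' Deterministic term-frequency hashing (lowercased alphanumeric tokens
#' hashed into `dim` buckets) with inverse-document-frequency weighting and
#' L2 normalisation. IDF weights are computed over the input batch unless
#' supplied (queries against a [CorpusIndex-class] reuse the corpus IDF).
#' Zero-length texts yield a zero vector with a warning.
#'
#' @param texts character vector.
#' @param dim embedding dimensionality (default 512).
#' @param idf optional IDF vector of length `dim`.
#' @return numeric matrix, one L2-normalised row per text.
#' @export
embedTexts <- function(texts, dim = 512L, idf = NULL) {
  if (!length(texts)) stop("texts must be nonempty")
  .embed_matrix(texts, dim, idf)$vectors
}

#' Build a searchable index over an ingested corpus
#'
#' Chunks every document, embeds all chunks with the hashed TF-IDF
#' embedder, and stores vectors plus corpus IDF weights for consistent
#' query embedding.
#'
#' @param docs data.frame from [ingestCorpus()].
#' @param cfg A [RetrievalConfig-class].
#' @return A [CorpusIndex-class].
#' @export
indexCorpus <- function(docs, cfg = retrievalConfig()) {
  stopifnot(is.data.frame(docs), nrow(docs) >= 1L)
  chunks <- do.call(rbind, lapply(seq_len(nrow(docs)), function(i)
    chunkDocument(docs$text[i], cfg, docs$doc_id[i])))
  emb <- .embed_matrix(chunks$text, cfg@embedDim)
  new("CorpusIndex",
      documents = docs[, c("doc_id", "source", "title", "nchar")],
      chunks = chunks, vectors = emb$vectors, idf = emb$idf, config = cfg)
}

setMethod("show", "CorpusIndex", function(object) {
  cat(sprintf("CorpusIndex: %d documents, %d chunks, dim %d (%s)\n",
              nrow(object@documents), nrow(object@chunks),
              object@config@embedDim, object@config@embedder))
})

#' Maximal marginal relevance selection
#'
#' Greedy MMR over candidate vectors: the first pick maximises cosine
#' similarity to the query; each subsequent pick maximises
#' \eqn{\lambda \cos(q, c) - (1 - \lambda) \max_{s \in selected}
#' \cos(c, s)}. Ties break toward the lowest candidate index. With
#' \eqn{\lambda = 1} the result is a plain top-k similarity sort.
#'
#' @param query query vector.
#' @param candidates matrix of candidate vectors (one per row).
#' @param lambda relevance-diversity trade-off in \[0, 1\].
#' @param k number of selections.
#' @return integer vector of `min(k, nrow(candidates))` distinct indices in
#'   selection order.
#' @export
mmrSelect <- function(query, candidates, lambda = 0.5, k = 4L) {
  stopifnot(k >= 1L, nrow(candidates) >= 1L)
  cos <- function(a, b) {
    na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
    if (na == 0 || nb == 0) 0 else sum(a * b) / (na * nb)
  }
  simq <- apply(candidates, 1, cos, b = query)
  k <- min(k, nrow(candidates))
  selected <- integer(0)
  remaining <- seq_len(nrow(candidates))
  for (step in seq_len(k)) {
    obj <- if (!length(selected)) {
      simq[remaining]
    } else {
      vapply(remaining, function(ci) {
        red <- max(vapply(selected, function(si)
          cos(candidates[ci, ], candidates[si, ]), numeric(1)))
        lambda * simq[ci] - (1 - lambda) * red
      }, numeric(1))
    }
    pick <- remaining[which.max(obj)]  # which.max takes the first (lowest index) tie
    selected <- c(selected, pick)
    remaining <- setdiff(remaining, pick)
  }
  selected
}

#' Retrieve diverse supporting excerpts for one feature
#'
#' Embeds the query "\<feature description\> \<property\>" with the corpus
#' IDF weights and runs MMR over all chunks. When no chunk shows
#' non-trivial similarity (max cosine < 0.05, e.g. the query vocabulary is
#' absent from the corpus), the result is flagged low-confidence.
#'
#' @param description humanized feature description.
#' @param property target property name.
#' @param index A [CorpusIndex-class].
#' @return A [RetrievalResult-class].
#' @export
retrieveForFeature <- function(description, property, index) {
  stopifnot(is(index, "CorpusIndex"))
  if (!nrow(index@chunks)) stop("empty corpus index")
  cfg <- index@config
  q <- embedTexts(paste(description, property), dim = cfg@embedDim,
                  idf = index@idf)[1, ]
  sims <- as.numeric(index@vectors %*% q)  # rows are L2-normalised
  sel <- mmrSelect(q, index@vectors, cfg@lambda, cfg@kRetrieve)
  out <- index@chunks[sel, c("doc_id", "chunk_index", "text")]
  out$similarity <- sims[sel]
  rownames(out) <- NULL
  new("RetrievalResult", query = paste(description, property),
      chunks = out, lowConfidence = max(sims) < 0.05)
}
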