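#' @include retrieval.R globalize.R
NULL

.templateVersion <- "cx-template-1"
.disclaimer <- "an explicit relationship was not found in the given documents"

# Direction keyword vocabulary shared by the mock generator and the
# free-text parser; versioned with the template.
.positiveKeywords <- c("increase", "increases", "increased", "enhance",
                       "enhances", "enhanced", "improve", "improves",
                       "raises", "promotes", "higher")
.negativeKeywords <- c("decrease", "decreases", "decreased", "reduce",
                       "reduces", "reduced", "lower", "lowers",
                       "diminishes", "suppresses")

#' Assemble the stuffed chain-of-thought prompt
#'
#' Renders one evidence block per impactful feature: the humanized
#' description, the direction suggested by the attribution analysis, and
#' the MMR-selected literature excerpts in selection order, each tagged
#' with its source document and chunk. The task instructions walk the
#' generator through intermediate steps: state the correlation direction,
#' propose a mechanism, cite only the provided excerpts, and emit the
#' verbatim disclaimer when no evidence supports a feature. Features with
#' zero retrieved excerpts are still included, with an explicit
#' `NO_EVIDENCE` marker. Rendering is deterministic.
#'
#' @param featureSet data.frame from [topFeatures()].
#' @param retrievals named list of [RetrievalResult-class], one per feature
#'   (missing/NULL entries become empty-evidence blocks).
#' @param property target property name.
#' @return A [PromptBundle-class].
#' @export
assemblePrompt <- function(featureSet, retrievals, property) {
  stopifnot(nrow(featureSet) >= 1L)
  blocks <- lapply(seq_len(nrow(featureSet)), function(i) {
    rr <- retrievals[[featureSet$feature[i]]]
    ex <- if (!is.null(rr) && nrow(rr@chunks)) rr@chunks else NULL
    list(feature = featureSet$feature[i],
         description = featureSet$description[i],
         direction = featureSet$direction[i],
         excerpts = ex)
  })
  names(blocks) <- featureSet$feature
  preamble <- paste0(
    "You are a chemistry research assistant. Using ONLY the literature ",
    "excerpts provided below, explain how each listed molecular feature ",
    "relates to the target property '", property, "'.")
  instructions <- paste(
    "Work through the following steps for each feature:",
    "1. Restate the feature and the direction suggested by the attribution analysis.",
    "2. Scan the provided excerpts for an explicit directional claim about the feature.",
    "3. State the correlation direction (positive, negative, or unclear).",
    "4. Propose a physicochemical mechanism consistent with the evidence.",
    "5. Cite only the provided excerpts, using their [CITE doc=... chunk=...] tags.",
    paste0("6. If no excerpt supports the feature, state verbatim: '",
           .disclaimer, "'."),
    sep = "\n")
  new("PromptBundle", preamble = preamble, blocks = blocks,
      instructions = instructions, templateVersion = .templateVersion,
      property = property)
}

#' Render a PromptBundle to the prompt text
#'
#' Byte-deterministic rendering used by all backends; excerpt order follows
#' MMR selection order.
#'
#' @param object A [PromptBundle-class].
#' @param ... unused.
#' @return single character string.
#' @name promptText
#' @aliases promptText,PromptBundle-method
#' @export
setMethod("promptText", "PromptBundle", function(object, ...) {
  render_block <- function(b, i) {
    ev <- if (is.null(b$excerpts)) {
      "NO_EVIDENCE"
    } else {
      paste(vapply(seq_len(nrow(b$excerpts)), function(j) {
        sprintf("[E%d doc=%s chunk=%d] %s", j, b$excerpts$doc_id[j],
                b$excerpts$chunk_index[j],
                gsub("\n", " ", b$excerpts$text[j]))
      }, character(1)), collapse = "\n")
    }
    paste0("## FEATURE ", i, "\n",
           "NAME: ", b$feature, "\n",
           "DESCRIPTION: ", b$description, "\n",
           "DIRECTION_FROM_XAI: ", b$direction, "\n",
           "EVIDENCE:\n", ev)
  }
  paste0(object@preamble, "\n\nTARGET_PROPERTY: ", object@property, "\n\n",
         paste(vapply(seq_along(object@blocks), function(i)
           render_block(object@blocks[[i]], i), character(1)),
           collapse = "\n\n"),
         "\n\n", object@instructions,
         "\n\nTEMPLATE: ", object@templateVersion, "\n")
})

# Sentence templates for the mock generator; the seed picks one variant per
# feature so repeated runs differ in phrasing but not in substance.
.mockPhrasings <- list(
  positive = c(
    "A higher value of %s is associated with an increased %s.",
    "The evidence indicates that %s tends to raise %s.",
    "Molecules exhibiting %s show elevated %s in the cited work."),
  negative = c(
    "A higher value of %s is associated with a decreased %s.",
    "The evidence indicates that %s tends to lower %s.",
    "Molecules exhibiting %s show reduced %s in the cited work."))

#' The deterministic mock generation backend
#'
#' An offline, fully deterministic stand-in for a hosted language model,
#' honouring the [GenerationBackend-class] contract: identical (prompt,
#' seed) yields identical text. It parses the prompt's feature blocks,
#' scans each block's excerpts for direction keywords ("increases",
#' "reduces", ...), and emits a fixed-format explanation with machine-
#' parseable `DIRECTION:` tags, citations of the supporting excerpt via its
#' `[CITE doc=... chunk=...]` tag, and the verbatim evidence-absent
#' disclaimer where no keyword evidence exists. The seed selects among
#' equivalent phrasings, so repeated runs vary in wording (exercising the
#' ROUGE-L variability protocol) without changing any direction claim.
#'
#' @return A [GenerationBackend-class] named `"mock"`.
#' @export
mockBackend <- function() {
  new("GenerationBackend", name = "mock", deterministic = TRUE,
      generator = function(prompt, seed) .mockGenerate(prompt, seed))
}

#' @rdname generate
#' @export
setMethod("generate", "GenerationBackend",
          function(backend, prompt, seed, ...) backend@generator(prompt, seed))

# First match of a single-line pattern, with its leading tag stripped.
.grabTag <- function(x, tag) {
  m <- regmatches(x, regexpr(paste0(tag, ": [^\n]+"), x))
  if (length(m)) sub(paste0("^", tag, ": "), "", m) else ""
}

# Parse the prompt's feature blocks back out of the rendered text.
.parsePromptBlocks <- function(prompt) {
  prop <- .grabTag(prompt, "TARGET_PROPERTY")
  parts <- strsplit(prompt, "## FEATURE [0-9]+\n")[[1]][-1]
  lapply(parts, function(p) {
    ev_lines <- grep("^\\[E[0-9]+ doc=", strsplit(p, "\n")[[1]], value = TRUE)
    ev <- if (length(ev_lines)) {
      data.frame(
        doc_id = sub("^\\[E[0-9]+ doc=([^ ]+) chunk=.*", "\\1", ev_lines),
        chunk_index = as.integer(
          sub("^\\[E[0-9]+ doc=[^ ]+ chunk=([0-9]+)\\].*", "\\1", ev_lines)),
        text = sub("^\\[E[0-9]+ doc=[^ ]+ chunk=[0-9]+\\] ", "", ev_lines),
        stringsAsFactors = FALSE)
    } else NULL
    list(feature = .grabTag(p, "NAME"), description = .grabTag(p, "DESCRIPTION"),
         direction = .grabTag(p, "DIRECTION_FROM_XAI"), evidence = ev,
         property = prop)
  })
}

.keywordDirection <- function(text) {
  low <- tolower(text)
  words <- .text_tokens(low)
  npos <- sum(words %in% .positiveKeywords)
  nneg <- sum(words %in% .negativeKeywords)
  if (npos > nneg) "positive" else if (nneg > npos) "negative" else "unclear"
}

.mockGenerate <- function(prompt, seed) {
  blocks <- .parsePromptBlocks(prompt)
  .with_seed(seed, {
    out <- vapply(blocks, function(b) {
      dir <- "unclear"; cite <- NULL
      if (!is.null(b$evidence)) {
        dirs <- vapply(b$evidence$text, .keywordDirection, character(1))
        hit <- which(dirs != "unclear")
        if (length(hit)) {
          dir <- dirs[hit[1]]
          cite <- b$evidence[hit[1], ]
        }
      }
      if (is.null(cite)) {
        hypo <- sprintf(
          "For %s, %s; its influence on %s therefore remains unquantified here.",
          b$description, .disclaimer, b$property)
      } else {
        phr <- sample(.mockPhrasings[[dir]], 1)
        hypo <- sprintf("%s [CITE doc=%s chunk=%d]",
                        sprintf(phr, b$description, b$property),
                        cite$doc_id, cite$chunk_index)
      }
      paste0("FEATURE: ", b$feature, "\n",
             "DESCRIPTION: ", b$description, "\n",
             "DIRECTION: ", dir, "\n",
             "HYPOTHESIS: ", hypo)
    }, character(1))
    paste0("GENERATED EXPLANATION (", .templateVersion, ")\n\n",
           paste(out, collapse = "\n\n"), "\n")
  })
}

# Parse generated text into per-feature hypothesis records. Structured
# DIRECTION: tags are used when present; otherwise the declared free-text
# rule applies: the sentence containing the feature description is scanned
# for direction keywords, else unclear.
.parseExplanationText <- function(text, featureSet) {
  n <- nrow(featureSet)
  direction <- rep("unclear", n)
  supported <- rep(FALSE, n)
  structured <- grepl("FEATURE: ", text, fixed = TRUE) &&
    grepl("DIRECTION: ", text, fixed = TRUE)
  if (structured) {
    parts <- strsplit(text, "FEATURE: ", fixed = TRUE)[[1]][-1]
    feat <- vapply(strsplit(parts, "\n"), `[[`, character(1), 1)
    dirs <- vapply(parts, .grabTag, character(1), tag = "DIRECTION")
    hyps <- vapply(parts, .grabTag, character(1), tag = "HYPOTHESIS")
    for (i in seq_len(n)) {
      k <- match(featureSet$feature[i], feat)
      if (!is.na(k)) {
        direction[i] <- dirs[k]
        supported[i] <- !grepl(.disclaimer, hyps[k], fixed = TRUE) &&
          grepl("[CITE", hyps[k], fixed = TRUE)
      }
    }
  } else {
    sentences <- strsplit(text, "(?<=[.!?])\\s+", perl = TRUE)[[1]]
    for (i in seq_len(n)) {
      hit <- grep(featureSet$description[i], sentences, fixed = TRUE)
      if (length(hit)) {
        direction[i] <- .keywordDirection(paste(sentences[hit], collapse = " "))
        supported[i] <- !any(grepl(.disclaimer, sentences[hit], fixed = TRUE))
      }
    }
  }
  data.frame(feature = featureSet$feature,
             description = featureSet$description,
             direction = direction, supported = supported,
             stringsAsFactors = FALSE)
}

#' Generate explanations over repeated seeded runs
#'
#' Runs the backend `nRuns` times with seeds `baseSeed, baseSeed + 1, ...`
#' and parses each output into per-feature hypothesis records. A backend
#' failure on a run is recorded as a failed run (empty text, all directions
#' unclear), never silently dropped.
#'
#' @param backend A [GenerationBackend-class].
#' @param bundle A [PromptBundle-class].
#' @param nRuns number of runs (default 5, the evaluation protocol).
#' @param baseSeed first run seed.
#' @return list of [Explanation-class], one per run.
#' @export
generateExplanations <- function(backend, bundle, nRuns = 5L, baseSeed = 1L) {
  stopifnot(is(backend, "GenerationBackend"), is(bundle, "PromptBundle"),
            nRuns >= 1L)
  prompt <- promptText(bundle)
  featureSet <- data.frame(
    feature = vapply(bundle@blocks, `[[`, character(1), "feature"),
    description = vapply(bundle@blocks, `[[`, character(1), "description"),
    stringsAsFactors = FALSE)
  lapply(seq_len(nRuns), function(r) {
    seed <- as.integer(baseSeed) + r - 1L
    txt <- tryCatch(backend@generator(prompt, seed), error = function(e) {
      warning("backend '", backend@name, "' failed on run ", r, ": ",
              conditionMessage(e))
      ""
    })
    hyp <- .parseExplanationText(txt, featureSet)
    new("Explanation", runId = sprintf("run_%d_seed_%d", r, seed),
        text = txt, hypotheses = hyp,
        citations = data.frame(key = character(0), doc_id = character(0),
                               chunk_index = integer(0),
                               feature = character(0), resolved = logical(0),
                               stringsAsFactors = FALSE))
  })
}

# Render a citation key "(FirstSourceToken, Year|n.d.)" from a doc title.
.renderCiteKey <- function(title) {
  tok <- regmatches(title, regexpr("[A-Za-z][A-Za-z-]+", title))
  yr <- regmatches(title, regexpr("(19|20)[0-9]{2}", title))
  sprintf("(%s, %s)", if (length(tok)) tok else "Unknown",
          if (length(yr)) yr else "n.d.")
}

#' Resolve citation markers against the corpus registry
#'
#' Scans the explanation text for structured `[CITE doc=... chunk=...]`
#' markers and free-text "Name et al. YYYY" citations. Markers whose
#' document and chunk exist in the index are replaced by a rendered key of
#' the form "(FirstSourceToken, Year)" (or "n.d." without a year) and
#' recorded as resolved citations; unresolvable markers are replaced by
#' `"[unresolved]"` and flagged. Total: never errors.
#'
#' @param explanation An [Explanation-class].
#' @param index A [CorpusIndex-class] (the corpus registry).
#' @return The explanation with rewritten text and a populated citation
#'   table (key, doc_id, chunk_index, feature, resolved).
#' @export
attachCitations <- function(explanation, index) {
  stopifnot(is(explanation, "Explanation"), is(index, "CorpusIndex"))
  txt <- explanation@text
  cites <- list()

  # a marker's feature is the closest preceding FEATURE: tag in the text
  m <- gregexpr("\\[CITE doc=([^ ]+) chunk=([0-9]+)\\]", txt)[[1]]
  if (m[1] != -1L) {
    markers <- regmatches(txt, gregexpr("\\[CITE doc=([^ ]+) chunk=([0-9]+)\\]",
                                        txt))[[1]]
    heads <- gregexpr("FEATURE: [^\n]+", txt)[[1]]
    head_names <- if (heads[1] != -1L)
      sub("^FEATURE: ", "",
          regmatches(txt, gregexpr("FEATURE: [^\n]+", txt))[[1]]) else character(0)
    for (i in seq_along(markers)) {
      doc <- sub("\\[CITE doc=([^ ]+) chunk=.*", "\\1", markers[i])
      chk <- as.integer(sub(".*chunk=([0-9]+)\\]", "\\1", markers[i]))
      feat <- NA_character_
      if (length(head_names)) {
        prior <- which(heads <= m[i])
        if (length(prior)) feat <- head_names[max(prior)]
      }
      ok <- doc %in% index@documents$doc_id &&
        any(index@chunks$doc_id == doc & index@chunks$chunk_index == chk)
      key <- if (ok)
        .renderCiteKey(index@documents$title[index@documents$doc_id == doc])
      else "[unresolved]"
      txt <- sub(markers[i], key, txt, fixed = TRUE)
      cites[[length(cites) + 1L]] <- data.frame(
        key = key, doc_id = doc, chunk_index = chk, feature = feat,
        resolved = ok, stringsAsFactors = FALSE)
    }
  }

  # free-text "Name et al. 1999" style citations
  ft <- regmatches(txt, gregexpr("[A-Z][A-Za-z-]+ et al\\.?,? \\(?(19|20)[0-9]{2}\\)?",
                                 txt))[[1]]
  for (marker in unique(ft)) {
    tok <- sub(" et al.*", "", marker)
    hit <- grep(paste0("\\b", tok, "\\b"), index@documents$title)
    ok <- length(hit) > 0L
    if (!ok) txt <- gsub(marker, "[unresolved]", txt, fixed = TRUE)
    cites[[length(cites) + 1L]] <- data.frame(
      key = if (ok) .renderCiteKey(index@documents$title[hit[1]])
            else "[unresolved]",
      doc_id = if (ok) index@documents$doc_id[hit[1]] else marker,
      chunk_index = if (ok) 0L else NA_integer_, feature = NA_character_,
      resolved = ok, stringsAsFactors = FALSE)
  }

  explanation@text <- txt
  explanation@citations <- if (length(cites)) do.call(rbind, cites) else
    explanation@citations
  explanation
}

#' Render the run report as markdown
#'
#' One deterministic markdown document: surrogate quality, the ranked
#' feature table, per-feature hypotheses with citations for each run, and
#' the reference list.
#'
#' @param explanations list of [Explanation-class] (after
#'   [attachCitations()]).
#' @param global A [GlobalImportance-class].
#' @param report An [EvalReport-class].
#' @param index A [CorpusIndex-class] for the reference list.
#' @param path output markdown path.
#' @return `path`, invisibly.
#' @export
renderReport <- function(explanations, global, report, index, path) {
  stopifnot(length(explanations) >= 1L, is(global, "GlobalImportance"),
            is(report, "EvalReport"))
  met <- paste(names(report@metrics),
               sprintf("%.4f", unlist(report@metrics)),
               sep = " = ", collapse = ", ")
  imp <- importanceTable(global)
  lines <- c(
    "# Structure-property explanation report", "",
    "## Surrogate model",
    sprintf("Task: %s. Holdout (%d rows): %s.", report@taskKind,
            report@testSize, met), "",
    "## Ranked features",
    "| rank | feature | score | direction |",
    "|---|---|---|---|",
    sprintf("| %d | %s | %.5f | %s |", imp$rank, imp$feature, imp$score,
            imp$direction), "",
    "## Generated explanations")
  for (ex in explanations) {
    lines <- c(lines, "", sprintf("### %s", ex@runId), "", "```",
               ex@text, "```")
  }
  refs <- index@documents
  lines <- c(lines, "", "## References",
             sprintf("- %s `%s` (%s)", refs$title, refs$doc_id, refs$source))
  writeLines(lines, path)
  invisible(path)
}
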