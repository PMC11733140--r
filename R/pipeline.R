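#' @include evaluation.R
NULL

#' Build and validate a run configuration
#'
#' One flat configuration for the end-to-end pipeline; validated before
#' any stage runs and serialized verbatim into the output directory. The
#' single master seed is fanned out deterministically to per-stage seeds
#' (split, SHAP background, LIME sampling, generation runs).
#'
#' @param input path to the input CSV (or a [MoleculeTable-class]).
#' @param corpus path to the literature corpus directory.
#' @param outDir output directory for all artifacts.
#' @param labelColumn,smilesColumn CSV column names (ignored for tables).
#' @param taskKind optional task override.
#' @param xaiMethod `"shap"`, `"lime"` or `"both"`.
#' @param k number of impactful features to explain (default 3).
#' @param backend backend name; only `"mock"` is built in.
#' @param nRuns generation runs (default 5).
#' @param seed master seed.
#' @param property target property name used in queries and prompts.
#' @param catalog A [FeatureCatalog-class] for feature readability.
#' @return validated configuration list of class `chemxplain_config`.
#' @export
runConfig <- function(input, corpus, outDir, labelColumn = "label",
                      smilesColumn = NULL, taskKind = NULL,
                      xaiMethod = c("shap", "lime", "both"), k = 3L,
                      backend = "mock", nRuns = 5L, seed = 1L,
                      property = "the target property",
                      catalog = NULL) {
  xaiMethod <- match.arg(xaiMethod)
  if (!is(input, "MoleculeTable") && !file.exists(input))
    stop("config error: input not found: ", input)
  if (!dir.exists(corpus))
    stop("config error: corpus directory not found: ", corpus)
  if (backend != "mock")
    stop("config error: unknown backend '", backend, "'")
  stopifnot(k >= 1L, nRuns >= 1L)
  structure(list(input = input, corpus = corpus, outDir = outDir,
                 labelColumn = labelColumn, smilesColumn = smilesColumn,
                 taskKind = taskKind, xaiMethod = xaiMethod,
                 k = as.integer(k), backend = backend,
                 nRuns = as.integer(nRuns), seed = as.integer(seed),
                 property = property,
                 catalog = catalog %||% featureCatalog()),
            class = "chemxplain_config")
}

# Spearman rank agreement between two importance rankings.
.rankAgreement <- function(g1, g2) {
  t1 <- importanceTable(g1); t2 <- importanceTable(g2)
  stats::cor(t1$rank[order(t1$feature)], t2$rank[order(t2$feature)],
             method = "spearman")
}

#' Run the full explanation pipeline
#'
#' Executes data loading, surrogate training, attribution, globalization,
#' retrieval, generation, citation resolution and evaluation under one
#' seeded configuration, writing all artifacts and a manifest of content
#' hashes into the output directory. With the mock backend and a fixed
#' master seed the artifact hashes are byte-identical across reruns.
#' `xaiMethod = "both"` runs SHAP and LIME and additionally reports their
#' Spearman rank agreement; SHAP ranks drive the explained feature set.
#'
#' @param config from [runConfig()].
#' @return the run manifest (list): per-stage artifact paths, md5 content
#'   hashes, metric summaries, per-stage wall time and warnings.
#' @export
#' @examples
#' \donttest{
#' tab <- generateSynthetic(syntheticSpec(n = 200, d = 6, support = c(1, 4),
#'                                        weights = c(1.5, -1.5),
#'                                        noiseSd = 0.1, seed = 1))
#' corp <- tempfile()
#' syntheticCorpus(c("f1", "f4"), c("positive", "negative"),
#'                 "solubility", corp)
#' cfg <- runConfig(tab, corp, tempfile(), property = "solubility",
#'                  seed = 7)
#' man <- runPipeline(cfg)
#' names(man$artifacts)
#' }
runPipeline <- function(config) {
  stopifnot(inherits(config, "chemxplain_config"))
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  seeds <- .fan_seed(config$seed,
                     c("split", "background", "lime", "generation"))
  manifest <- list(config = config[setdiff(names(config), "catalog")],
                   seeds = as.list(seeds), stages = list(),
                   artifacts = character(0), hashes = character(0),
                   warnings = character(0))
  art <- function(name, path) {
    manifest$artifacts[name] <<- path
    manifest$hashes[name] <<- unname(tools::md5sum(path))
  }
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    manifest$stages[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    out
  }

  table <- stage("data", {
    if (is(config$input, "MoleculeTable")) config$input
    else loadTable(config$input, config$labelColumn, config$smilesColumn,
                   config$taskKind)
  })

  fit <- stage("surrogate", fitSurrogate(table, splitSeed = seeds[["split"]]))
  evalPng <- file.path(config$outDir, "eval_plot.png")
  exportEvalPlot(fit$report, evalPng); art("eval_plot", evalPng)

  attrib <- stage("attribution", {
    train <- table[match(fit$model@trainIds, table@rowIds), ]
    res <- list()
    if (config$xaiMethod %in% c("shap", "both"))
      res$shap <- globalize(localTreeShap(
        fit$model, table, background = train,
        seed = seeds[["background"]]))
    if (config$xaiMethod %in% c("lime", "both"))
      res$lime <- globalize(localLime(
        fit$model, limeSample(table, seed = seeds[["lime"]]),
        seed = seeds[["lime"]]))
    res
  })
  global <- attrib$shap %||% attrib$lime
  impCsv <- file.path(config$outDir, "importances.csv")
  utils::write.csv(importanceTable(global), impCsv, row.names = FALSE)
  art("importances", impCsv)
  impPng <- file.path(config$outDir, "importance_plot.png")
  exportImportancePlot(global, impPng); art("importance_plot", impPng)

  index <- stage("retrieval_index",
                 indexCorpus(ingestCorpus(config$corpus)))
  top <- topFeatures(global, config$catalog, k = min(config$k, ncol(table)))
  retrievals <- stage("retrieval", {
    rr <- lapply(seq_len(nrow(top)), function(i)
      retrieveForFeature(top$description[i], config$property, index))
    names(rr) <- top$feature
    rr
  })

  explanations <- stage("generation", {
    bundle <- assemblePrompt(top, retrievals, config$property)
    backend <- mockBackend()
    ex <- generateExplanations(backend, bundle, nRuns = config$nRuns,
                               baseSeed = seeds[["generation"]])
    lapply(ex, attachCitations, index = index)
  })
  reportMd <- file.path(config$outDir, "report.md")
  renderReport(explanations, global, fit$report, index, reportMd)
  art("report", reportMd)

  evaluation <- stage("evaluation", {
    tally <- tallyHypotheses(explanations)
    prec <- hypothesisPrecision(tally)
    rouge <- if (config$nRuns >= 2L) rougeVariability(explanations) else NULL
    audit <- auditCitations(explanations, index, config$catalog)
    list(tally = as.data.frame(tally@counts),
         precision = prec$precision,
         rouge_mean = if (!is.null(rouge)) rouge$mean else NA_real_,
         rouge_sd = if (!is.null(rouge)) rouge$sd else NA_real_,
         citation_total = audit$total, citation_correct = audit$correct,
         citation_unresolved = sum(!audit$citations$resolved))
  })
  evalJson <- file.path(config$outDir, "eval.json")
  jsonlite::write_json(evaluation, evalJson, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  art("evaluation", evalJson)

  manifest$metrics <- c(fit$report@metrics,
                        evaluation[setdiff(names(evaluation), "tally")])
  if (config$xaiMethod == "both")
    manifest$metrics$rank_agreement <- .rankAgreement(attrib$shap,
                                                      attrib$lime)
  manifest$hyperparameters <- fit$model@hyperparameters
  manifestJson <- file.path(config$outDir, "manifest.json")
  jsonlite::write_json(manifest, manifestJson, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, force = TRUE)
  .log("pipeline complete: ", config$outDir)
  manifest
}
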