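# chemxplain

Literature-grounded natural-language explanations of structure–property
relationships from tabular molecular data.

Chemists routinely fit black-box models to structure–property data, but a
feature-attribution plot is not a scientific explanation. `chemxplain`
automates the workflow a scientist would follow instead: fit a surrogate
model, find out *which* structural features drive the predicted property,
look up what the literature says about those features, and write down
cited, directional hypotheses — flagging explicitly when the provided
documents contain no supporting evidence. It is aimed at cheminformatics
and materials researchers who have a feature table (molecular descriptors,
or SMILES to be featurized into MACCS keys) and a folder of relevant
papers.

## Method

1. **Surrogate.** A gradient-boosted tree ensemble (XGBoost; fixed,
   audited hyperparameters; deterministic single-thread training) maps the
   feature matrix X to the property y, with holdout metrics (RMSE/R² or
   accuracy/F1) and an error plot.
2. **Attribution.** Local explanations by interventional tree SHAP
   (computed exactly from the ensemble's leaves, so local accuracy
   `base + Σⱼ φᵢⱼ = f(xᵢ)` holds to machine precision) and/or LIME
   (perturb-and-fit local linear surrogates on a ≤500-row sample). Local
   attributions are aggregated globally: `Gⱼ = meanᵢ|φᵢⱼ|` for SHAP,
   cross-feature Z-scores of mean absolute weights for LIME, with a
   direction call (positive / negative / unclear) from the signed mean.
   A `2^d` exact-Shapley subset enumeration is included as a test oracle.
3. **Retrieval.** The literature corpus is chunked (1000 characters,
   200 overlap), embedded with a deterministic hashed TF-IDF embedder, and
   queried per feature with maximal marginal relevance
   (`argmax λ·cos(q,c) − (1−λ)·maxₛ cos(c,s)`).
4. **Generation.** Top-k features + retrieved excerpts are stuffed into a
   versioned chain-of-thought prompt and passed to a pluggable generation
   backend. The built-in mock backend is fully deterministic and offline;
   it derives each direction claim from keyword evidence in the excerpts,
   cites only provided excerpts, and emits the verbatim disclaimer
   *"an explicit relationship was not found in the given documents"* when
   evidence is absent.
5. **Evaluation.** Hypothesis precision over repeated runs
   (`1/(N_features·N_runs) Σᵢ |nᵢ,pos − nᵢ,neg|`, weights +1/−1/0),
   ROUGE-L (LCS-based F1) variability across runs, and a structural
   citation audit (resolved against the corpus registry; supported by
   substring evidence in the cited chunk).

## Worked example

```r
library(chemxplain)

# synthetic data with a planted truth: f1 raises, f4 lowers the property
tab <- generateSynthetic(syntheticSpec(n = 300, d = 6, support = c(1, 4),
                                       weights = c(1.5, -1.5),
                                       noiseSd = 0.1, seed = 5))
corpus <- tempfile()
syntheticCorpus(c("f1", "f4"), c("positive", "negative"),
                "aqueous solubility", corpus)

man <- runPipeline(runConfig(tab, corpus, "out/",
                             property = "aqueous solubility", seed = 7))
unlist(man$metrics[c("r2", "precision", "rouge_mean", "citation_total",
                     "citation_unresolved")])
#>                  r2           precision          rouge_mean
#>           0.9874721           1.0000000           0.7320268
#>      citation_total citation_unresolved
#>          15.0000000           0.0000000
```

The surrogate explains 98.7% of the holdout variance; across 5 generation
runs every per-feature direction claim was consistent (precision 1.0, the
maximum of the +1/−1/0 score); wording varied between runs (mean pairwise
ROUGE-L 0.73) without changing any claim; and all 15 citations resolved to
documents in the corpus. The rendered report (`out/report.md`) contains,
for the top-ranked feature:

```
FEATURE: f1
DIRECTION: positive
HYPOTHESIS: A higher value of f1 is associated with an increased aqueous
solubility. (Rivera, 2011)
```

which is the planted ground truth, cited to the synthetic document that
asserts it. With real data, replace the synthetic table with
`loadTable("X.csv", labelColumn = "label")` (or SMILES input via
`smilesColumn`, featurized into the 167 MACCS keys and humanized through
`maccsCatalog()`), and point `corpus` at a directory of `.txt`/`.md`
articles. A command-line front end is installed at
`inst/scripts/chemxplain` (`chemxplain run --input X.csv --label label
--corpus papers/ --out report/`).

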