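---
title: "Methods: explainable surrogates with literature-grounded hypothesis generation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: explainable surrogates with literature-grounded hypothesis generation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chemxplain)
```

`chemxplain` turns a tabular molecular dataset and a folder of literature
into cited, directional structure–property hypotheses. This vignette
documents the model, the tunable parameters and their defaults, the
numerical choices, and what the synthetic test bed does and does not
establish about real data.

## The surrogate model

The unknown structure–property mapping is approximated by a
gradient-boosted tree ensemble (XGBoost): `reg:squarederror` for
regression, `binary:logistic` for classification, 100 rounds, depth 6,
learning rate 0.3, no subsampling, exact greedy splits, one thread. The
hyperparameters are deliberately hardcoded — the tool targets
non-specialists, and a fixed, audited configuration (exposed read-only in
every run manifest) keeps results reproducible bit-for-bit; there is no
early stopping or tuning. Exact single-threaded training is slower than
the histogram method but removes the last source of nondeterminism.
Evaluation uses a seeded 20% holdout, stratified by class for
classification, and reports RMSE/R² or accuracy/F1 on the holdout only.
The fit ceiling matters downstream: a surrogate that has learned spurious
structure will hand spurious features to every later stage, which is why
the holdout report and parity plot are first-class outputs.

## Local attributions

**Tree SHAP (interventional).** Attributions use the interventional
(background-marginalised) value function: the value of a coalition is the
mean model output with coalition features fixed to the explained row and
all other features drawn from a background sample. For a tree ensemble
this expectation is computable exactly: along each root-to-leaf path the
unique features split into those where only the explained row satisfies
the path conditions (a of them) and those where only the background row
does (b of them), and such a leaf contributes its value with the
closed-form Shapley weights `(a−1)!·b!/(a+b)!` (positive side) and
`−a!·(b−1)!/(a+b)!` (background side). Summing over leaves, trees and
background rows gives attributions that satisfy local accuracy
(`base + Σφ = prediction`) to floating-point precision; the test suite
checks them against a `2^d` subset-enumeration oracle at `d ≤ 8` with a
1e-6 tolerance (residual differences come from float32 leaf storage in
the ensemble dump). For classification, attributions live in the additive
log-odds margin space, recorded in the attribution metadata: margin space
preserves additivity across trees, which both the closed form and the
efficiency identity require; probabilities are a monotone transform, so
rankings are unaffected.

Defaults: background = 100 seeded rows (the training split in the
pipeline), attributed rows capped at a seeded sample of 500. The row cap
mirrors the LIME sampling protocol below — exact interventional SHAP costs
O(rows × background × ensemble size) and a 500-row sample estimates the
global mean-|φ| ranking with ample margin at the problem sizes we target.

**LIME.** Each sampled row is explained by a weighted ridge regression
(penalty 1.0 on standardised features) fitted to 200 perturbations, each
perturbed feature keeping its value with probability 0.5 and otherwise
resampling from the column's empirical marginal; proximity weights are
exponential with kernel width `0.75·√d` on standardised distances (the
conventional LIME tabular kernel). LIME explains at most 500 rows — the
entire dataset when smaller — drawn uniformly without replacement under a
seed.

## Global importance and direction calls

SHAP globalises as the mean absolute attribution `G_j = meanᵢ|φᵢⱼ|`. LIME
first takes per-feature mean absolute weights and then standardises them
*across features* into Z-scores, scoring `max(z_j, 0)` and ranking by
`z_j`. The cross-feature convention (rather than per-feature
across-instance standardisation) is a deliberate interpretation — both
yield rankings, and only one can be the default; it is flagged here
because the underlying convention is genuinely open. Direction is called
from the mean signed attribution with a relative dead-band
`δ = 0.01·max_j G_j`: above +δ positive, below −δ negative, otherwise
unclear. The dead-band prevents calling a direction from numerically tiny
signed means; magnitude uses mean-|φ| while sign uses the signed mean,
since the two answer different questions. Rank ties break
lexicographically by feature name so output order is deterministic. The
top k = 3 features (configurable) are explained, matching the convention
of reporting a small named feature set.

## Retrieval

Documents (`.txt`/`.md`; PDFs are skipped — no text extractor is bundled)
are chunked by a sliding character window: size 1000, overlap 200, stride
`size − overlap`, preferring to cut at whitespace within 50 characters
before the nominal boundary when that leaves no coverage gap.
Concatenating de-overlapped chunks reconstructs the document exactly
(property-tested). Chunks are embedded with a deterministic offline
embedder: lowercased alphanumeric tokens hashed into 512 buckets, TF
counts weighted by corpus IDF, L2-normalised. Hashing trades a bounded
collision risk for a fixed dimension and zero vocabulary state; the
orthogonality of disjoint vocabularies is asserted at < 0.05 cosine.
Per-feature queries (`<description> <property>`) are answered by maximal
marginal relevance with λ = 0.5 and k = 4 excerpts, ties toward the lower
candidate index; λ = 1 degenerates to a plain similarity sort (tested
extensionally). All retrieval constants are declared defaults: chunking
policy, λ, k and the embedder are not dictated by any external convention,
and remote embedding services would break offline reproducibility, so
they sit behind the same embedder contract as optional adapters.

## Generation and citations

The prompt stuffs each feature's description, attribution direction and
tagged excerpts into a versioned chain-of-thought template
(`cx-template-1`): restate the feature, scan the evidence, state the
direction, propose a mechanism, cite only provided excerpts, and emit the
verbatim disclaimer "an explicit relationship was not found in the given
documents" when unsupported. Features with no retrieved excerpts carry an
explicit `NO_EVIDENCE` marker rather than being dropped — silence must be
distinguishable from absence of retrieval.

Backends implement `generate(prompt, seed) → text`. The deterministic
mock backend is a first-class implementation, not a test shim: it reads
direction keywords ("increases", "reduces", …) from the provided excerpts,
cites the supporting excerpt's `[CITE doc= chunk=]` tag, seeds a choice
among equivalent phrasings (so repeated runs vary in wording but never in
claims — exactly what the ROUGE-L variability protocol needs), and emits
machine-parseable `DIRECTION:` tags. Free-text outputs from other
backends are parsed by a declared rule: the sentence containing the
feature description is scanned for the same keyword vocabulary, else the
direction is unclear. Citation markers are resolved against the corpus
registry into `(FirstSourceToken, Year)` keys; unresolvable markers
become `[unresolved]` and are flagged, never invented.

## Evaluation

Across `N_runs = 5` seeded runs, per-feature direction labels are tallied
(features absent from a run count as unclear, keeping the denominator
well-defined) and scored as
`precision = 1/(N_features·N_runs) · Σᵢ |nᵢ,pos − nᵢ,neg|` — the +1/−1/0
weighting of positive/negative/unclear labels, bounded in [0, 1].
Labels come from the structured direction fields of parsed explanations,
making the metric fully automatic; the keyword parser is the declared
stand-in for manual labelling. ROUGE-L uses whitespace tokens and the F1
(β = 1) convention over all unordered run pairs; tokenization and β are
stated because the metric is convention-sensitive. The citation audit is
structural by design: resolved means the document is registered, supported
means the cited chunk contains the feature description (case-insensitive
substring) — semantic entailment is out of scope, and the audit reports
raw and per-explanation-normalised accuracy side by side because the
normalisation across studies is itself ambiguous.

## The synthetic test bed

`generateSynthetic()` draws d independent Bernoulli(0.5) binary features
and a label from a sparse planted linear form `η = Σ_{j∈S} w_j x_j`
(regression: `y = η + N(0, σ²)`; classification:
`y ~ Bernoulli(logistic(η + b))` with b centring prevalence at 0.5).
Balanced features and prevalence are chosen so attribution-recovery tests
are not confounded by class imbalance. `syntheticCorpus()` writes short
documents asserting directional claims about named features in controlled
vocabulary, plus distractor documents. The reference study conditions for
support recovery are n = 2000, d = 20, |S| = 3, |w| = 1.5, σ = 0.1 over
20 generator seeds; oracle comparisons use n = 250–500 and d ≤ 8 where
`2^d` enumeration is exact.

What passing these tests shows: the attribution machinery is numerically
correct, the pipeline is deterministic, and the generation/evaluation path
is structurally sound (claims grounded, citations resolvable,
disclaimers emitted). What it does not show: real molecular features are
correlated, real labels are not linear in binary bits, real literature is
not written in controlled vocabulary, and a keyword parser underestimates
what a capable language model can support or contradict. Results on the
synthetic bed are a floor for machinery correctness, not a forecast of
explanation quality on laboratory data.

## Degenerate inputs and numerical edges

Classification with a single label class, fewer than 10 rows, empty
corpora, and over-long coalitions (`d > 12` for exact enumeration) are
hard errors. Zero-variance LIME score spreads yield all-zero Z-scores
with a warning; zero-length texts embed to zero vectors with a warning;
constant models attribute (numerically) nothing. Rows failing validation
are dropped with reason codes, never imputed — surrogate fidelity is
preferred over data retention.

## Known limitations

The MACCS featurizer depends on OpenBabel's substructure definitions
(numbering verified against the common 167-key convention); no other
fingerprint is provided. The offline embedder has no semantics beyond
token overlap, so retrieval recall on paraphrased literature is limited
by vocabulary. The mock backend cannot weigh conflicting evidence beyond
keyword counts. PDF corpora must be converted to text externally. And the
hypothesis-precision metric measures consistency, not truth: a
confidently wrong generator scores 1.
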