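Package: chemxplain
Title: Literature-Grounded Natural-Language Explanations of
    Structure-Property Relationships
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Trains a gradient-boosted-tree surrogate on tabular molecular
    data (precomputed descriptors or MACCS keys featurized from SMILES),
    extracts globally impactful features from local SHAP and LIME
    attributions, retrieves supporting excerpts from a literature corpus by
    maximal marginal relevance over hashed TF-IDF embeddings, generates
    cited structure-property hypotheses through a pluggable text-generation
    backend (with a deterministic offline mock), and scores the generated
    explanations by hypothesis precision, ROUGE-L variability and a
    structural citation audit. Includes an exact-Shapley enumeration oracle
    and a synthetic-data generator with a planted sparse feature-label
    relationship for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    ggplot2,
    xgboost,
    ChemmineOB,
    jsonlite,
    withr,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
biocViews: Cheminformatics, MachineLearning, FeatureExtraction
RoxygenNote: 7.3.3
Collate: 
    'utils.R'
    'AllGenerics.R'
    'AllClasses.R'
    'MoleculeTable-methods.R'
    'RcppExports.R'
    'surrogate.R'
    'attribution.R'
    'chemxplain-package.R'
    'data-io.R'
    'globalize.R'
    'retrieval.R'
    'explanation.R'
    'evaluation.R'
    'pipeline.R'
    'synthetic.R'
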