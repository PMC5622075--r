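Package: GrwLDA
Title: Global Network Random Walk Prediction of lncRNA-Disease Associations
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Predicts candidate associations between long non-coding RNAs
    (lncRNAs) and diseases by dual random walks with restart on a
    heterogeneous network built from MeSH-derived disease semantic
    similarity, lncRNA functional similarity, and experimentally verified
    associations. Provides DAG-based disease semantic similarity, the
    LNCSIM group-wise lncRNA functional similarity, column-stochastic
    network propagation with Laplacian-smoothed seed vectors, leave-one-out
    and k-fold cross-validation protocols (including novel-lncRNA and
    isolated-disease modes), ROC/PR evaluation, case-study ranking, and a
    synthetic benchmark generator with planted block structure.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'accessors.R'
    'data-io.R'
    'similarity.R'
    'propagation.R'
    'evaluation.R'
    'synthetic.R'
    'cli.R'
    'GrwLDA-package.R'
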