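Package: fatecourse
Title: Fate Inference for Time-Course Single-Cell Transcriptomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis workflow for inferring how postmitotic neuronal
    precursors diversify into discrete terminal types from a developmental
    time course of single-cell RNA-seq. Provides quality filtering and
    median normalization, Gamma-Poisson highly-variable-gene selection,
    random-matrix-theory guided dimensionality choice, graph-based
    clustering with differential-expression driven refinement, per-age
    diversity and cluster-distinctiveness statistics, supervised cross-age
    cluster correspondence (adjusted Rand index, normalized conditional
    entropy, occupancy fractions), entropic unbalanced optimal transport
    between ages with fate vectors and a multipotentiality potential,
    fate-coupling networks with randomization nulls and logistic decay
    fits, specification-time estimation, and ipsilateral/contralateral
    signature analysis. Includes a synthetic time-course generator with a
    planted fate tree so every estimator can be validated against known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    FNN,
    xgboost,
    minpack.lm,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    mclust,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
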