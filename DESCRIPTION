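Package: klsnet
Title: Individual Structural Covariance Networks from Kullback-Leibler
    Similarity of Regional Morphometry
Version: 0.1.0
Authors@R:
    person("klsnet", "developers", email = "klsnet@example.org",
           role = c("aut", "cre"))
Description: Builds individual (single-subject) structural covariance
    networks from regional morphometric value distributions using a
    symmetric Kullback-Leibler divergence mapped through an exponential
    transform (KLS), profiles binary-graph topology across sparsity
    thresholds with degree-preserving null-model normalization, runs
    covariate-adjusted group statistics with FDR control, and classifies
    mild-cognitive-impairment subtypes with leak-free nested
    cross-validation and LASSO feature selection.  Ships a calibrated
    synthetic cohort generator emulating post-segmentation ROI-level data
    for three diagnostic groups (CN, EMCI, LMCI) so the whole pipeline is
    exercisable without access to gated imaging repositories.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    data.table,
    igraph,
    glmnet,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
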