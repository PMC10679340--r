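Package: connreg
Title: Partially Localized Regression Models for Brain Functional Connectivity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Subject-level regression models that explain pairwise functional
    connectivity (Fisher-Z transformed inter-regional correlations) from
    region-pair covariates: smooth terms in geographic and homotopic distance,
    region-involvement indicators, and functional-network membership
    indicators. Provides orderings-averaged (LMG/Shapley) decomposition of the
    proportion of variation explained into covariate-group contributions,
    per-predictor relative importance, and discriminability (test-retest
    repeatability) estimation for ordered edge vectors (Euclidean distance),
    model fitted values, and edge distributions (2-Wasserstein distance),
    together with a permutation reference distribution and a synthetic
    multi-subject, multi-session connectome generator with known additive
    structure.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    mgcv,
    yaml,
    jsonlite,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
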