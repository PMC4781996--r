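Package: scnet
Title: Structural Covariance Network Analysis of Regional Brain Morphometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Builds group-level structural covariance networks from
    subject-by-region morphometric feature tables (cortical thickness,
    volume, area, curvature, metric distortion, sulcal depth): covariate
    residualization, Ledoit-Wolf shrinkage covariance inverted to partial
    correlations, proportional-threshold binarization across a sparsity
    sweep, small-world and betweenness-centrality graph metrics compared
    against degree-preserving rewired null models, and nonparametric
    permutation tests for between-group differences.  A synthetic
    two-group cohort generator with block-structured covariance supports
    validation without imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
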