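Package: mbindex
Title: Hierarchical Multipurpose Biomarker Indices for Multi-Endpoint
    Toxicologic Pathology
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds composite toxicity indices from heterogeneous
    morphological, morphometric and ultrastructural endpoints measured on
    exposure groups.  Each feature is z-scored across group representative
    values, aligned so that larger scores mean greater pathological
    alteration, and pooled as replicates into organ-level subindices
    (e.g. nephrotoxic, thyrotoxic, immunotoxic) and a global multipurpose
    index.  Inference on the pooled scores uses tie-corrected
    Kruskal-Wallis tests with rank epsilon-squared effect sizes,
    Monte Carlo permutation p-values, Dunn pairwise comparisons with Holm
    adjustment and rank-biserial correlations.  Includes area-fraction and
    cell-proportion quantification helpers, a synthetic feature-table
    generator for power/operating-characteristic simulation, radar-plot
    reporting and a scriptable pipeline driver.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    yaml
Suggests:
    optparse,
    png,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
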