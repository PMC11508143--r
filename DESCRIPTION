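Package: tscoex
Title: Two-State Weighted Gene Co-Expression Network Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds weighted gene co-expression networks from time-series
    RNA-seq count matrices under two conditions (control and salt stress),
    following the classical WGCNA recipe: median-of-ratios normalization, a
    variance-stabilizing log transform, high-variance gene filtering,
    soft-threshold selection by scale-free topology fit, topological overlap,
    average-linkage module detection, module eigengenes and module-trait
    relationships. Separate normal-state and stress-state networks are
    thresholded into graphs; degree, betweenness, closeness and clustering
    coefficient are compared between states to identify stress-emergent key
    hub genes, and module gene sets are tested for over-representation
    against user-supplied GMT annotations. A synthetic-data generator with
    planted modules and stress-emergent hubs makes the whole pipeline
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    mclust,
    stats,
    tools,
    utils
Suggests:
    DESeq2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
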