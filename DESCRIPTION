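Package: alans
Title: Construction of a Lateralized Visuospatial Attention Network Atlas
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds an atlas of lateralized brain networks from region-level
    task-fMRI contrasts and resting-state time series. Regions are retained by
    a Bonferroni-corrected conjunction of activation and hemispheric-asymmetry
    tests on homotopic region pairs, clustered into intrinsic networks by
    Ward-linkage hierarchical clustering of a Fisher-averaged connectivity
    matrix with a multi-index vote on the cluster count, coupled across
    networks by exact binomial sign tests, and characterised topologically by
    weighted degree and betweenness centrality with a mean-plus-one-SD dual
    threshold for hub detection. A deterministic synthetic-cohort generator
    emulates the homotopic pair structure, planted activation and asymmetry
    effects, block-modular resting-state covariance and band-limited noise of
    such studies, so every stage is testable against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    igraph,
    cluster,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    signal
Config/testthat/edition: 3
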