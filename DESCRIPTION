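Package: roirank
Title: Rank Regions of Interest on Histology Slides for Targeted Spatial Transcriptomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Ranks candidate regions of interest (ROIs) on H&E whole-slide
    images for targeted spatial-transcriptomics sequencing. Combines the
    visual diversity of patch embeddings (median pairwise distance in a
    UMAP-reduced space) with the cellular diversity of a nucleus cell-type
    map (density-weighted Shannon entropy), or, for hypothesis-driven
    searches, text-prompt similarity with target-cell abundance. Includes
    zero-shot and active-learning nucleus classification, expression-derived
    ground-truth rankings from spot-level count matrices, top-K ranking
    metrics with bootstrap confidence intervals, and a fully seeded
    synthetic slide generator so the entire pipeline runs offline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    Matrix,
    jsonlite,
    stats,
    utils,
    xgboost,
    uwot,
    rhdf5,
    arrow
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
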