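Package: AortaCrosstalk
Title: Cell-Cell Crosstalk Analysis for Aortic Dissection Single-Cell Data
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Reusable pipeline for inferring fibroblast-to-smooth-muscle-cell
    crosstalk from multi-donor, two-condition (non-dissected versus dissected
    aorta) single-cell UMI count data. Implements cell and gene quality
    filtering, size-factor log normalization, one-vs-rest Wilcoxon marker
    detection with Benjamini-Hochberg adjustment, a principal-axis pseudotime
    stand-in with condition-composition state assignment, hypergeometric GO
    enrichment, secreted-ligand extraction with a z-score secreting-capacity
    statistic, a GO cross-match linking cluster ligands to trajectory-state
    biology, and product-of-means ligand-receptor interaction scoring between
    condition-split cell populations. A negative-binomial simulator with
    planted clusters, ligands, receptors and trajectory programs provides a
    ground-truth testbed.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    jsonlite,
    yaml,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
biocViews: SingleCell, Transcriptomics, CellBiology, DifferentialExpression
RoxygenNote: 7.3.3
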