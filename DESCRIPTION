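Package: imctme
Title: Single-Cell Imaging Mass Cytometry Analysis of the Tumor
    Microenvironment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end single-cell analysis of multiplexed imaging mass
    cytometry (IMC) data: hot-pixel removal and percentile normalization,
    random-forest pixel classification into nuclei/cytoplasm/background
    probability maps, watershed-based cell segmentation, per-cell marker
    quantification with explicit quality-control rules, phenograph-style
    clustering (Jaccard-weighted kNN graph plus Louvain) with marker-based
    phenotype annotation, per-ROI abundance comparison, and a
    border-distance permutation test for spatial enrichment or depletion
    of phenotype pairs. Ships a synthetic-data generator that renders
    IMC-like regions of interest with known ground truth so the full
    pipeline is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    igraph,
    Matrix,
    matrixStats,
    methods,
    RANN,
    ranger,
    stats,
    tiff,
    utils,
    uwot
Suggests:
    jsonlite,
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
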