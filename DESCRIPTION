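Package: mirafe
Title: Pre-Processing and Differential Expression Analysis of Agilent
    microRNA Microarrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Reads Agilent Feature Extraction (AFE) text exports for
    single-color microRNA microarrays, assembles probe-level datasets, and
    assesses array quality (probe-replicate coefficient of variation, MA and
    relative log expression values against a median reference array, sample
    clustering). Signals are pre-processed by either between-array
    normalization of the AFE total gene signal or a robust multiarray average
    with optional normal plus exponential background correction, quantile
    normalization and median-polish summarization. Genes are filtered on AFE
    detection flags and negative-control expression thresholds, and
    differential expression is assessed with gene-wise linear models,
    contrasts and empirical-Bayes moderated t-statistics with multiple-testing
    adjustment. A synthetic data generator emulating the Human miRNA
    Microarray v2.0 design provides ground-truth datasets for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    limma,
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
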