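Package: hruv
Title: Hierarchical Removal of Unwanted Variation for Multi-Batch LC-MS
    Metabolomics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Replicate-aware experimental design and hierarchical
    normalization for large multi-batch liquid chromatography-mass
    spectrometry metabolomics studies. Generates run-order design sheets
    that embed pooled quality-control samples, intra-batch (short) sample
    replicates and inter-batch (batch) replicates; corrects within-batch
    signal drift per metabolite with robust linear or loess smoothers or
    the pooled-QC ratio method; removes unwanted variation with a
    replicate-anchored factor model (RUV-III) applied hierarchically over
    a balanced or concatenating merge tree; and evaluates normalization
    with replicate standard deviations, sample skewness, batch-clustering
    adjusted Rand index, relative log expression and principal-component
    diagnostics. Includes a multi-batch simulator with known drift, batch
    shifts and biological effects for ground-truth benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    MASS,
    stats,
    graphics,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    e1071,
    jsonlite,
    optparse
Config/testthat/edition: 3
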