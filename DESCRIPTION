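Package: pemscreen
Title: Screening Deletion Calls for False Positives with Paired-End Mapping Evidence
Version: 0.1.0
Authors@R:
    person("Maintainer", "pemscreen", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects likely false-positive deletion calls in DGV-style
    structural-variant catalogues. Chromosome-wide binned GC-content and
    mappability tracks are smoothed and segmented into bias-suspicious
    regions; catalogued deletions falling inside such regions (base-level
    overlap F-score > 0.9) are re-validated against paired-end read-mapping
    evidence extracted from coordinate-sorted alignment files, and calls
    without sufficient well-mapped spanning pairs are classified as false
    positives. Includes a seeded, truth-labelled synthetic-data generator
    (profile tracks, alignment files, variant tables) so the whole pipeline
    is testable without external downloads, plus reporting utilities
    (per-variant diagnostic figures, summary statistics, Gaussian-mixture
    fits of the false-positive size distribution).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    data.table,
    jsonlite,
    BiocGenerics,
    IRanges,
    GenomicRanges,
    S4Vectors,
    Rsamtools,
    GenomicAlignments,
    rtracklayer
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
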