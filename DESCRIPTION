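Package: eccell
Title: Detection and Single-Cell Assignment of Extrachromosomal DNA from
    scATAC-seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects candidate extrachromosomal DNA (ecDNA) amplicons from
    barcoded single-cell ATAC-seq libraries treated as a pseudo-bulk sample
    (coverage segmentation, discordant read-pair clustering, clip-position
    refinement and breakpoint-graph cycle assembly), then assigns each
    candidate ecDNA to individual cells with a dip test of unimodality
    followed by a two-component Gaussian mixture model or gene-score k-means
    clustering, validated against discordant-read gold-standard cells by
    Fisher's exact test. Includes read-level and Poisson count-matrix
    simulators of focal amplification, a sliding-window single-cell
    copy-number estimator, and a benchmarking harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomicAlignments,
    Rsamtools,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse
Config/testthat/edition: 3
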