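Package: rpwmtr
Title: Detection of Highly Divergent Tandem Repeats with Random Position
    Weight Matrices
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Detects highly divergent tandem repeats in DNA sequences by
    optimizing randomly generated position weight matrices with a genetic
    algorithm against sliding windows. Windows are scored by affine-gap
    dynamic-programming alignment of the sequence to the tandem-extended
    matrix; triplet-periodic (mostly coding) windows are excluded with a
    chi-square mutual-information filter; repeat regions are called as
    two-dimensional local maxima of the score surface over window position
    and period. Shuffle-based Z statistics, FDR threshold calibration,
    synthetic benchmark generators with planted repeats, and Monte-Carlo
    interval-overlap enrichment statistics are included.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
biocViews: Genetics, SequenceMatching, Alignment, RepeatAnalysis
RoxygenNote: 7.3.3
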