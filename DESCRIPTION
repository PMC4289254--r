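Package: chromseg
Title: Genome Segmentation by Chromatin Compactness from Differential
    DNase I Sensitivity Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Segments a genome into open, closed and neutral chromatin
    domains from probe-level differential DNase I sensitivity signals on
    tiling arrays.  Two segmentation models are provided: a two-configuration
    model (2CM) that detects transition points with a sliding-window
    statistic calibrated against probe permutations, and a
    three-configuration model (3CM) that calls signal peaks with a
    two-state Gaussian hidden Markov model, filters them by an empirical
    false discovery rate, and consolidates same-sign peak clusters into
    domains separated by neutral segments.  Downstream tools compute
    cumulative base-pair overlaps of the domains with annotation tracks
    (lamina-associated domains, chromatin states, histone-modification
    regions), and relate domains to gene expression via RPKM-based
    activity classification, gene and intron size categories, positional
    intron profiles, and the tissue-specificity index tau.  A synthetic
    data generator with planted ground truth supports parameter-recovery
    testing of the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    Rcpp,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
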