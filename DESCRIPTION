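Package: exocnv
Title: Copy Number Variant Detection from Whole-Exome Read Depth
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Multi-sample normalization and copy number variant (CNV)
    calling for whole-exome sequencing read depth. Fits a Poisson
    latent-factor null model that removes biases due to GC content,
    exon capture and amplification efficiency, and latent systemic
    artifacts, with the number of latent factors chosen by information
    criteria. CNVs are called by a Poisson generalized-likelihood-ratio
    circular binary segmentation with a modified BIC stopping rule, and
    genotyped as fractional or integer copy numbers. Includes exon
    coverage extraction from BAM files, target-level quality control,
    a case-control mode, and a spike-in simulator for power and
    specificity benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    methods,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    Rcpp,
    Biostrings,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    Rsamtools,
    S4Vectors,
    rtracklayer
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
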