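Package: crehmm
Title: Supervised Constrained Hidden Markov Models for Enhancer and
    Promoter Prediction from Chromatin Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts active enhancers and promoters genome-wide from
    chromatin accessibility (ATAC-seq or DNase-seq) and three histone
    modification tracks (H3K27ac, H3K4me1, H3K4me3). Foreground sub-models
    with an enforced nucleosome - accessible - nucleosome (N1 -> A -> N2)
    topology are learned in a supervised two-step procedure (unconstrained
    five-state fit, emission-based state selection, constrained Viterbi
    training with frozen log-normal emissions) and composed with an
    unsupervised ten-state background model into a single constricted HMM.
    Includes binned signal extraction from BAM files, quantile
    normalization across samples, training- and test-region construction
    from CAGE regions, peak calls and gene annotation, Viterbi
    segmentation with posterior accessibility scores, precision-recall
    evaluation, and a fully synthetic data generator for end-to-end
    validation without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    methods,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    jsonlite,
    withr,
    ggplot2,
    generics,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Rsamtools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
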