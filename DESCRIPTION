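Package: songqtl
Title: Courtship Song Trait Differentiation and QTL Mapping in Fly Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for analysing quantitative courtship
    song traits in Drosophila population panels and recombinant inbred lines
    (RILs). Provides recording-level quality filtering and strain trait tables,
    Mann-Whitney population comparisons with a family-wise min-p permutation
    correction, Qst estimation and comparison against per-SNP Fst
    distributions, additive single-QTL LOD scans over RIL ancestry windows
    with permutation-based genome-wide thresholds, peak merging with inclusive
    and restrictive 1.5-LOD support intervals extended through masked windows,
    residual trait mapping for correlated traits, windowed population-genetic
    differentiation statistics (full-window Fst, maximum-SNP Fst, comparative
    haplotype identity) with per-arm outlier calls, exon-based gene-window
    annotation, and synthetic-data generators with known ground truth for
    calibration and parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    MASS,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    IRanges,
    jsonlite,
    knitr,
    rtracklayer,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
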