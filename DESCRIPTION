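Package: temark
Title: Benchmarking Toolkit for Transposable-Element Read Mapping and Quantification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to benchmark how read aligners and counting strategies handle
    transposable-element (TE) derived sequencing reads. Reconstructs TE copies
    from RepeatMasker annotation (including LTR/internal dictionary pairing and
    fragment merging), generates synthetic genomes with planted TE families of
    controlled divergence, simulates Illumina-like paired-end reads with exact
    ground truth, aligns them with a brute-force micro-aligner in unique,
    random and multi reporting modes, scores alignments with hit-weighted
    true-positive metrics, and quantifies TE families under unique, random,
    fractional and total counting modes against the known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    stringr,
    rlang,
    generics,
    ggplot2,
    Rcpp,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    Rsamtools,
    methods,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
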