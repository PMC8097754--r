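Package: haplomosaic
Title: Simulation-Based Appraisal of Ancestral Haplotype Reconstruction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A self-contained pipeline for judging how accurately ancestral
    haplotype maps can be reconstructed from sparse genotype data in
    multi-parent crossing designs. The package simulates known-truth,
    origin-labelled diplotypes by meiosis down a user-specified pedigree,
    corrupts them with a global genotyping-error rate and per-locus
    missingness, imputes missing calls with a haplotype-reference hidden
    Markov model and filters markers on estimated imputation quality,
    reconstructs the founder-of-origin mosaic of every individual with a
    joint two-homologue hidden Markov model (Viterbi paths and posterior
    parent certainty), and scores the reconstruction against the simulated
    truth with ancestral, genotype and phase assignment accuracies plus the
    correlation between known and inferred crossover counts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    tidyr,
    tibble,
    purrr,
    readr,
    ggplot2,
    rlang,
    stats,
    methods,
    utils,
    generics,
    jsonlite,
    yaml,
    vcfR
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
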