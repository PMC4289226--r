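Package: venomforge
Title: Venom-Gland Transcriptome Assembly, Proteomic Validation and
    Selection Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A reusable pipeline for characterizing snake venom-gland
    transcriptomes from short paired-end reads: 3'-overlap read merging
    with adapter read-through removal, greedy seed-extension and
    reference-guided consensus assembly, toxin transcript clustering at
    <1% coding-sequence divergence, chimera screening, coding-sequence
    read-mapping abundance estimation, proteomic cross-validation of
    transcripts against peptide-identification reports with decoy-based
    acceptance filters, and molecular-evolution analyses (reciprocal
    best-hit orthologs, Nei-Gojobori and maximum-likelihood pairwise
    dN/dS, nontoxin null-distribution outlier tests, and codon
    site-model likelihood-ratio tests M1a/M2a and M7/M8).  A fully
    seeded synthetic-data generator produces two-species transcriptomes,
    read sets and identification reports with known ground truth so
    every stage is testable without external sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    Rcpp,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
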