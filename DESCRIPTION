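Package: svgenotyper
Title: Simulation-Driven Genotyping of Structural Variants from Short Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genotypes previously discovered, sequence-resolved deletion and
    insertion structural variants (SVs) in paired-end short-read sequencing
    data. For each putative SV the package simulates sequencing replicates for
    every zygosity, matched to the sample's read length, error rate, insert
    size distribution, and coverage; extracts realignment, spanning read-pair,
    soft-clip, and depth fold-change evidence identically from simulated and
    actual alignments; trains per-sample and per-variant classifiers on the
    simulated evidence; and predicts the genotype with a Phred-scaled quality.
    Also provides breakpoint-proposal refinement for deletions in tandem
    repeats, call-set matching and concordance evaluation, Mendelian-error
    analysis for trios, and a fully synthetic fixture generator so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    IRanges,
    Rcpp,
    dplyr,
    e1071,
    generics,
    ggplot2,
    purrr,
    randomForest,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    Rsamtools,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
LinkingTo: Rcpp
Config/testthat/edition: 3
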