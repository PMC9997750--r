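Package: symbiocensus
Title: Census and Evolutionary Analysis of Multiply Co-Infecting Endosymbionts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A desk-scale pipeline for censusing maternally transmitted
    bacterial endosymbionts (Wolbachia, Cardinium, 'Ca. Tisiphia',
    Rhabdochlamydia and relatives) in multiply infected arthropod hosts from
    shotgun read depth. Implements coverage-normalized symbiont-load
    estimation against a single-copy host marker gene with an
    accessory-gene restriction for near-identical strain pairs subject to
    cross-mapping, single-linkage ortholog-family clustering and
    core/accessory pangenome partition, fragment-based ANI and
    reciprocal-best-hit AAI species delimitation, per-family transposase
    phylogenetics with neighbor-joining and bootstrap for classifying
    cross-genome sharing as recent transfer versus ancient sister-clade
    co-residence, and fixed-variant density summaries. A seeded
    synthetic-data generator emulates the statistical structure of the
    underlying sequencing experiment and provides truth tables for
    parameter-recovery tests.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    ape,
    igraph,
    jsonlite,
    Rcpp,
    Biostrings,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn
SystemRequirements: NCBI BLAST+ (blastp, blastn, makeblastdb on PATH)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
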