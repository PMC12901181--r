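Package: integronArrays
Title: Detection and Classification of Unusual Recombination Sites in
    Integron Gene Cassette Arrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Sequence-analysis pipeline for integron variable regions:
    strand-aware degenerate (IUPAC) motif scanning, detection and
    crossover-relative classification of truncated attI (Delta-attI)
    recombination sites, attC site modelling by bottom-strand arm
    alignment with extrahelical-base calling, cassette-array assembly
    with architecture typing and tandem-duplicate detection, corpus-level
    survey summaries, and replicate frequency statistics for in vivo
    recombination assays (mean +/- SD over colony-PCR replicates,
    pairwise Welch's t-tests and significance letter groups). Includes a
    ground-truth synthetic integron generator so every stage is testable
    end to end without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    igraph,
    yaml,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
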