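Package: cassette
Title: Cassette-Exon Skipping Quantification and Evolution from Junction-Spanning Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies inclusion and skipping of short cassette exons (such as
    exon 6 of vertebrate D2-family dopamine receptor genes) directly from
    RNA-Seq reads, using 30-nt exon-junction queries matched at perfect
    identity, beta-actin control normalization, and a read-identity QC
    classifier for chimeric and rearranged artifacts. Also provides intron
    phase computation and detection of exon deletion by recombination between
    flanking phase-0 introns on protein alignments, a sliding-window local
    protein conservation score, parsimony gain/loss counting of a binary
    exon-skipping character on rooted species trees, and a seeded read
    simulator with truth labels for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    ape,
    dplyr,
    tidyr,
    purrr,
    tibble,
    stringr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    methods,
    stats,
    tools,
    utils
Suggests:
    phangorn,
    yaml,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
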