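Package: crucivir
Title: Discovery and Characterization of Cruciviruses from Circular Metagenomic Contigs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to identify and characterize cruciviruses and cruci-like
    circular genetic elements (CruCGEs) in assembled metagenomic data.
    Resolves circular genomes from terminally redundant contigs, screens
    them for tombusvirus-like capsid proteins, calls open reading frames
    under standard and ciliate genetic codes with splice-candidate rescue,
    detects and scores nonanucleotide-bearing stem-loop origins of
    rolling-circle replication, profiles the conserved HUH-endonuclease and
    superfamily-3 helicase motifs of Rep, partitions capsid proteins into
    R/S/P domains, and quantifies diversity through pairwise-identity
    matrices, threshold clustering and E-value similarity networks. A
    synthetic-genome generator with full ground truth makes every detector
    testable end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
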