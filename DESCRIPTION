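Package: nematax
Title: Taxonomic Profiling of Individual Soil Nematodes from Multi-Region 18S Amplicons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for specimen-level DNA barcoding of soil nematodes from deep
    amplicon sequencing of four regions of the 18S small-subunit (SSU) rRNA
    gene. Provides in-silico PCR with IUPAC-degenerate primers, per-sample
    quality control of sequence-variant (SV) tables, resolution of minor SVs
    into polymorphic rDNA alleles versus second nematodes, clustering of
    isolates into SSU-derived operational taxonomic units (rOTUs),
    neighbor-joining phylogenies with bootstrap support over regional and
    concatenated sequences, order and feeding-type assignment from reference
    trees, and an order-cluster-count metric for comparing trees. A seeded
    synthetic-community generator supplies ground-truthed reference sets and
    SV tables for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
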