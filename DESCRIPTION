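Package: paleovir
Title: Authentication and Comparative Genomics of Ancient Phage Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for recovering and analysing bacteriophage genomes from
    ancient metagenomes. Implements terminal C-to-T deamination profiling and
    likelihood-based authentication of ancient contigs, fragment-based average
    nucleotide identity (ANI) with greedy species-level vOTU clustering,
    amino-acid identity (AAI) graphs with Markov clustering at genus and
    family ranks, a binomial genome-conservation probability model, pairwise
    genome comparison (SNV calling, sliding-window identity, per-gene
    identity, core/flank separation), and read-level microdiversity
    statistics (nucleotide diversity, divergent sites). A bundled simulator
    generates ancient-style damaged read sets and evolved genome communities
    with full truth tables so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    Biostrings,
    igraph,
    jsonlite,
    methods,
    Rcpp,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    optparse,
    mclust,
    rtracklayer,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
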