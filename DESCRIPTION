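Package: baculoannot
Title: Annotation and Comparative Analysis of Small Circular Viral Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for annotating circular double-stranded DNA virus genomes
    (granuloviruses and other baculoviruses) and comparing them across a genome
    panel. Implements six-frame ORF enumeration on circular sequences with
    greedy minimal-overlap selection, granulin-anchored coordinate conventions,
    scanning for canonical baculovirus early (TATA + CAGT initiator) and late
    ((A/T/G)TAAG) promoter motifs, protein-level homology via local alignment
    and reciprocal best hits, gene classification over genome panels, k-mer
    dot-plot synteny, gene-order conservation (conserved runs and breakpoint
    distances), and concatenated-gene maximum-parsimony phylogenies with
    bootstrap support. A seeded synthetic-genome generator with planted ground
    truth makes every pipeline stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    phangorn,
    purrr,
    rlang,
    rtracklayer,
    stats,
    tibble,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
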