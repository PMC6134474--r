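Package: markerforge
Title: Design and Evaluation of Protein-Coding Phylogenetic Markers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A pipeline for establishing protein-coding phylogenetic
    markers in bacteria: conserved-block discovery in protein multiple
    alignments, consensus-clamp/degenerate-core (CODEHOP-style) PCR
    primer design with IUPAC ambiguity codes, in-silico amplification
    against nucleotide templates, Kimura 2-parameter distances,
    neighbour-joining tree construction with nonparametric bootstrap
    support, and Robinson-Foulds congruence assessment across marker
    trees. Includes a seeded synthetic-data generator (species trees,
    multi-rate marker alignments, hsp70-like protein families with
    planted conserved blocks) so the whole pipeline is testable without
    any sequence download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    seqinr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
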