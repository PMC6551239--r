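Package: txrecover
Title: Recovering Similar Transcripts from De Bruijn Graphs of RNA-Seq Reads
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds a condensed de Bruijn graph from RNA-Seq reads and
    recovers transcripts similar to those of a related organism directly
    from the graph, without a separate transcript-prediction step. Seed
    nodes are chosen by local-alignment hits against a transcript database
    (nucleotide or protein, via six-frame translated search), greedily
    extended one node at a time in the direction that improves the
    Karlin-Altschul e-value, extended likewise from the twin
    (reverse-complement) node, and merged. Per database transcript the best
    path is reported, trimmed to the aligned nodes. Includes a synthetic
    transcriptome/read simulator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
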