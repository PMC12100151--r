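Package: tandemtally
Title: Tandem Gene Array Length Profiling from Plasmid Long Reads
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measures the intrinsic instability of a tandem gene array cloned
    onto a linearized centromeric plasmid, using long reads. Selects target
    reads that span the whole array together with both vector flanks (so read
    clipping cannot bias the estimate), counts repeat units per read by
    seed-and-extend banded alignment, and summarises contraction and expansion
    frequencies across replicates with Welch tests. Ships an in-silico
    restriction digestion model and a seeded nanopore-like read simulator
    (error, clipping and background-molecule models) that emits FASTQ plus a
    truth table for validation.
License: MIT
Encoding: UTF-8
Imports:
    BiocGenerics,
    Biostrings,
    IRanges,
    Rcpp,
    jsonlite,
    methods,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
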