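Package: cubscan
Title: Codon Usage Bias Analysis of Protein-Coding Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing synonymous codon usage bias in sets of
    protein-coding sequences grouped by taxon. Computes positional
    nucleotide composition (GC1/GC2/GC3), Wright's effective number of
    codons together with its GC3-expected value and the ENC ratio,
    relative synonymous codon usage with preferred/rare/over-represented
    classification, parity-rule-2 bias coordinates, GC12-versus-GC3
    neutrality regression, correspondence analysis of RSCU matrices, and
    protein-level properties (amino-acid usage, GRAVY, aromaticity).
    Includes a seeded synthetic coding-sequence generator with
    controllable GC3, codon-bias strength and mutation-versus-selection
    regimes so the whole pipeline can be exercised without external data,
    plus a one-call pipeline driver that writes a fixed layout of
    tab-separated report tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    grDevices,
    graphics,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    MASS,
    optparse,
    seqinr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
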