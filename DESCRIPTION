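Package: galregulon
Title: Information-Theoretic Discovery and Classification of GalR Operators
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for mapping the regulon of the Escherichia coli
    transcription factor GalR from sequence and tiling-array data:
    degenerate-consensus operator scanning with fixed critical positions and
    a mismatch budget, Schneider-style information analysis of aligned
    binding sites (Rsequence, Rfrequency, small-sample entropy correction,
    individual-information weight matrices and genome scanning), ChIP-chip
    bound-region calling with score-interpolated boundaries, tiling-array
    regulation classification by expression ratio, and positional
    classification of operators into gene-regulatory versus
    chromosome-anchoring sites. A seeded synthetic-data generator emulates
    each input so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
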