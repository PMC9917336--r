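Package: modbarcode
Title: Design, Assembly, Simulation and Decoding of Modular Combinatorial DNA Barcode Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for modular combinatorial DNA barcode libraries built from
    interchangeable double-stranded blocks joined by sticky-end overhangs.
    Enumerates and selects variable-region codes under Hamming and
    shifted-register Hamming constraints, compiles block oligos and assembles
    barcodes in silico, predicts off-target (deletion-variant) chimeric
    ligation products from junction-interface similarity, simulates nested
    overhang-PCR library preparation with UMI ("TrapTag") attachment and
    amplicon sequencing reads with configurable substitution/indel error
    models, and decodes reads by global alignment to an N-wildcard template
    with TrapTag demultiplexing, read classification, recovery counts,
    deletion profiles and substitution spectra.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    igraph,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
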