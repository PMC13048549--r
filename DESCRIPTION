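Package: unwindR
Title: In Silico Unwinding of miRNA Duplex Ends and Strand-Selection
    Prediction
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Computes thermodynamic end stabilities of microRNA duplexes by
    constrained RNA folding at physiological temperatures and uses the
    resulting unwinding energies in the twin-drive model to predict which
    duplex strand (5p or 3p arm) is selected as the Argonaute guide. Wraps
    the ViennaRNA command-line tools (RNAfold, RNAcofold, RNAeval) for
    minimum-free-energy folding, two-strand cofolding, hard-constrained
    folding and fixed-structure evaluation; generates the hard-constraint
    strings for full-structure pinning, hairpin-structure pinning and
    progressive 1-4 nucleotide end unwinding; compares duplex and hairpin
    structures across temperatures; and scores strand predictions against
    guide-strand annotations. Includes a deterministic generator of
    synthetic miRNA-like hairpins and duplexes with planted structure for
    testing without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
SystemRequirements: ViennaRNA (>= 2.4): RNAfold, RNAcofold and RNAeval on
    the PATH
biocViews: StructuralPrediction, Sequencing, SmallRNA, Software
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
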