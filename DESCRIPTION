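Package: glycoforge
Title: Combinatorial Glycoform Enumeration and Binding Analytics for
    Mucin Glycopeptides
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for designing glycopeptide epitope libraries on mucin
    tandem repeats such as the MUC1 variable-number tandem repeat.
    Enumerates all combinatorial assignments of O-glycan states (for
    example the Tn and sialyl-Tn tumour antigens) over the
    serine/threonine glycosylation sites of a repeat unit, counts
    positional isomers, renders and parses annotated glycopeptide
    strings, extracts candidate epitope windows with tandem-repeat
    deduplication, and computes theoretical glycopeptide masses, charge
    states and diagnostic fragment ions from elemental compositions.
    Antibody-binding analytics cover equilibrium dissociation constants
    from surface plasmon resonance rate constants, 1:1 Langmuir
    sensorgram simulation and global fitting, and four-parameter
    logistic ELISA dose-response fits with EC50 estimation.
License: MIT + file LICENSE
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Encoding: UTF-8
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
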