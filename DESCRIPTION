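Package: EcotypeSeq
Title: Demarcation of Putative Ecological Species from Deep Amplicon Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for demarcating putative ecological species
    (ecotypes) of hot-spring Synechococcus from deep single-locus (psaA)
    amplicon sequencing. Includes synthetic community and read simulators
    with homopolymer error models, frameshift artifact cleaning against an
    in-frame consensus reference, dereplication and high-frequency sequence
    selection, a Stable Ecotype Model coalescent simulator with
    simulation-based likelihood fitting and tree-based ecotype demarcation,
    per-sample ecotype abundance profiles, and ecological statistics
    (canonical correspondence analysis, permutation cluster tests, G-tests,
    binomial trend models) plus diel transcript normalization.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    Rcpp,
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    IRanges,
    ape,
    phangorn,
    vegan,
    yaml,
    jsonlite
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
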