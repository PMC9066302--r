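Package: syntrophr
Title: Multi-Scale Modelling of Amino-Acid Cross-Feeding Bacterial Consortia
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a coarse-grained proteome-allocation model of the
    bacterial stringent response (ppGpp-regulated partitioning of mRNA and
    protein between a metabolic sector with an amino-acid-export sub-sector
    and a ribosomal sector), couples it sequentially to a two-strain
    consumer-resource model of an amino-acid cross-feeding Escherichia coli
    consortium, and provides the interaction analytics used to characterise
    such communities: relative density against the line of additivity,
    through-origin quadratic interaction fits, optimal initial frequency,
    fluorescence-based strain abundance, mutualism/parasitism/competition
    classification, amino-acid checkerboards and stringent-response sweeps.
    Includes a synthetic plate-reader data generator so every analysis step
    is testable without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    pracma,
    rlang,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
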