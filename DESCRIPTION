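Package: contactforge
Title: Rotamer-Based Contact Degree, Contact Potentials, and
    Co-Evolution-Augmented Contact Prediction
Version: 0.1.0
Authors@R:
    person("contactforge", "developers", email = "dev@contactforge.invalid",
           role = c("aut", "cre"))
Description: Tools for analysing residue-residue contacts in protein
    structures. Implements the rotamer-based contact degree metric and
    three distance-based contact definitions (any-heavy 8 A, C-beta 8 A,
    side-chain centroid 6 A), derives statistical contact potentials
    from structure sets under any definition, scores decoy sets for
    native-structure discrimination, combines co-evolution scores (DCA
    direct information or MetaPSICOV precision scores) with
    MSA-averaged contact-potential energies into a hybrid contact
    predictor, and evaluates predictions via positive predictive value
    curves, sequence-separation bins, and contact-map diversity
    entropy. Includes seeded generators for synthetic structures,
    rotamer libraries, alignments, and decoys used by the test suite.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
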