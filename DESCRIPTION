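Package: regseqtools
Title: Design, Simulation and Analysis of Reg-Seq Promoter Mutagenesis Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for massively parallel reporter assays of bacterial
    promoters in the Reg-Seq style. Designs mutagenized promoter libraries
    with barcode assignments, simulates DNA/RNA barcode counts from
    thermodynamic (Boltzmann-weight) models of transcription with
    condition-dependent transcription-factor activity, reconstructs
    barcode-to-variant maps from paired reads, computes per-base mutual
    information footprints and expression-shift matrices, segments binding
    sites with a two-state hidden Markov model, detects emergent sigma70
    -10 elements created by single mutations, clusters regulatory responses
    across growth conditions, and ranks transcription-factor enrichment
    from DNA-pulldown mass-spectrometry abundance tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    Biostrings,
    jsonlite,
    yaml,
    ape
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
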