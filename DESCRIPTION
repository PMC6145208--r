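Package: methvalid
Title: Technical Validation Toolkit for Array-Based DNA Methylation Assays
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Implements the statistical machinery needed to technically
    validate an array-based DNA methylation assay in a clinical-laboratory
    setting: empirical per-CpG reference intervals and detectability
    classification, aberrant-methylation calling with a reportable-range
    floor, replicate-precision similarity statistics and proficiency-testing
    pass rules, detection p-values from background control probes,
    intensity-based (MU) sample quality control with max-margin threshold
    learning, and linear reportable-range calibration against whole-genome
    bisulfite sequencing. A synthetic-data module generates reference
    populations, technical replicates, paired WGBS/array data and probe
    intensity tables with realistic statistical structure so the entire
    validation pipeline can be exercised end-to-end without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
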