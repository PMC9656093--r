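Package: glycoquant
Title: Annotation and Quantification of MALDI-TOF Glycomics Peak Lists
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for large-scale serum N-glycomics by MALDI-TOF mass
    spectrometry. Enumerates candidate N-glycan compositions (oligomannose,
    hybrid, mannose-rich hybrid, complex and LacDiNAc classes) with
    linkage-resolved sialic acid residues produced by sialic acid
    linkage-specific alkylamidation (SALSA), computes theoretical masses for
    labeled, sodiated glycans, annotates instrument-exported peak lists
    within a mass tolerance, clusters replicate peaks across experiments
    into spectral IDs, quantifies via a spiked internal standard, fits
    per-glycan calibration lines with an R-squared filter, and drives batch
    analysis from 384-spot MALDI plate layout workbooks. Includes a
    synthetic-data generator so the full pipeline is testable without
    instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    readxl,
    stats,
    tools,
    utils,
    zip
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
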