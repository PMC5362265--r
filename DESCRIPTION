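Package: PICTquant
Title: Quantification of Protein Interactions from Imaging Complexes after
    Translocation (PICT) Assays
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools to quantify two-channel PICT live-cell imaging
    experiments in budding yeast: spot segmentation of RFP-tagged
    anchoring platforms and GFP-tagged prey proteins by local adaptive
    thresholding with morphological cleanup, computation of the
    colocalization-based recruitment score with replicate pooling,
    normalization and Welch t-tests across conditions, nuclear versus
    non-nuclear classification of recruited prey from intensity profiles
    between paired anchors, time-course analysis of complex
    assembly/disassembly (inter-measurement rates, exponential-decay and
    logistic fits, response-stage labeling), and ChIP-qPCR relative
    occupancy via dilution-series standard curves and a chained
    IP/input, control-region and reference-locus normalization. A
    synthetic-data generator produces two-channel fields and kinetic
    time courses with known ground truth so the whole pipeline is
    testable without raw microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    igraph,
    tiff,
    yaml,
    jsonlite,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
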