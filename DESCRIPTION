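Package: MechanoProbe
Title: AFM Force-Spectroscopy Analysis of Hydrogel Stiffness, ECM Tethering
    and Stiffness-Responsive Expression Signatures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for atomic force microscopy (AFM)
    characterisation of functionalised polyacrylamide hydrogels and the
    transcriptional signatures of substrate stiffness. Fits the Hertz
    contact model to approach force-distance curves to estimate Young's
    modulus; extracts single rupture events from retraction curves and
    classifies specific extracellular-matrix (ECM) tether ruptures against
    negative-control probes by a two-dimensional density-ratio criterion
    with median-filter smoothing; estimates the surface density of covalent
    ECM anchorage points from co-factor concentration; and computes
    gene-cluster statistics (cumulative log2 fold change, direction
    fractions, ERK-target concordance, permutation tests) on
    differential-expression tables. Includes seeded synthetic-data
    generators with known ground truth for validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
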