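Package: MyoTrack
Title: Contractility, Elasticity and Imaging Phenotyping of Differentiating Cardiomyocytes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for tracking iPSC-derived cardiomyocyte differentiation from
    label-free video, force spectroscopy and fluorescence imaging. Implements
    frame-difference contractility analysis of beating monolayers (motion traces,
    time-integrated motion maps, baseline correction, threshold-based motion-period
    detection, inter-cluster synchrony), Hertz spherical-indenter fitting of AFM
    approach force curves with quality-control filters and per-group aggregation,
    and fluorescence/densitometry quantification (minimum cross-entropy and fuzzy
    thresholding, patch segmentation, area-weighted intensities, mitochondrial
    network size classes, JC-1 ratiometric maps, nuclear masking, sarcomere band
    spacing, Ponceau-normalized blots). A synthetic-data module generates every
    input with recorded ground truth so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tiff
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
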