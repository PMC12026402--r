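Package: mkflow
Title: Imaging Flow Cytometry Identification of Megakaryocytes
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for identifying megakaryocytes and micromegakaryocytes in
    imaging flow cytometry data from bone-marrow samples. Implements
    morphometric feature extraction from multichannel event images (area,
    aspect ratio, diameter, raw max pixel, background-subtracted intensity,
    gradient RMS), spillover compensation estimated from single-stain
    controls, a hierarchical gating cascade (stable flow, saturation,
    viability/DNA, lymphocyte exclusion, CD41+/dump-, linear-discriminant
    singlet gating, focus), a small convolutional neural network that
    separates CD41 membrane-positive cells from CD41-negative cells with
    adherent platelets, confusion-matrix evaluation statistics, and a
    parametric synthetic event-image generator with per-event ground truth
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tiff,
    EBImage,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: FlowCytometry, CellBasedAssays, Classification, Software
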