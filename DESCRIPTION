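Package: mpmtiles
Title: Tile-Based Cancer Classification for Label-Free Multiphoton
    Microscopy of Breast Tissue
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for patch-based classification of label-free multiphoton
    excitation microscopy (MPM) images of breast tissue. Provides a spectral
    model mapping autofluorescence and second-harmonic-generation emission
    through band-pass detection channels, a synthetic phantom generator that
    renders mammary ducts, adipose cells, collagen fibers, carcinoma in situ,
    invasive nests and immune cells with per-pixel ground truth, per-image
    standardization and 64-tile cropping, a median-filter signal-to-noise
    blank-tile rule, a trainable small convolutional tile classifier, and
    evaluation utilities: confusion-matrix metrics, per-image malignant
    probability with ROC thresholding, Mann-Whitney U and Cohen's kappa.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports: methods, stats, utils, graphics, grDevices, tiff, jsonlite, Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), e1071, pROC, optparse
Config/testthat/edition: 3
biocViews: Software, Classification, CellBiology
RoxygenNote: 7.3.3
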