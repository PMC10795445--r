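Package: sgroi
Title: Automated Region-of-Interest Generation for Breast Surface-Guided Radiotherapy
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools to generate the optical-surface region of interest (ROI) used for
    patient setup and motion monitoring in surface-guided radiotherapy (SGRT) of the
    whole breast. Implements two automated ROI construction algorithms: a
    body-contour-based algorithm driven by regressed skeletal joint locations
    (collar joints and mid-spine) and a breast-contour-based algorithm driven by
    the superior-inferior extent of the delineated ipsilateral breast. Includes a
    procedural synthetic human body generator with ground-truth skeletons, coronal
    projection and randomized torso cropping to build training datasets, a small
    trainable joint-regression backbone with mean-per-joint-position-error (MPJPE)
    evaluation, Dice-similarity-coefficient comparison of ROIs, grid-search tuning
    of the superior/inferior boundary shifts, and a synthetic patient cohort
    generator for end-to-end evaluation without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    png,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'RcppExports.R'
    'utils.R'
    'AllClasses.R'
    'AllGenerics.R'
    'body.R'
    'imaging.R'
    'jointModel.R'
    'roi.R'
    'evaluation.R'
    'cohort.R'
    'config.R'
    'io.R'
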