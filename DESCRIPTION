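Package: tvpstage
Title: Three-View-Patch CNN Ensembles for Staging the Alzheimer Disease
    Spectrum from Structural MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Stages the Alzheimer disease spectrum (cognitively normal,
    asymptomatic AD, MCI due to AD, AD dementia) from labeled structural
    MRI volumes.  Brain regions are ranked by permutation-test p-values on
    regional morphometry, 2.5-D three-view patches (stacked axial, coronal
    and sagittal 32x32 windows) are extracted from the selected regions,
    lightweight convolutional neural networks are trained per region and
    binary task with a transfer-learning chain, and scan-level decisions
    are produced by two-level SoftMax score aggregation across patches and
    regions.  Includes a phantom-cohort simulator (ellipsoidal regions
    with class-dependent atrophy and intensity effects plus Gaussian
    morphometry tables) so the full pipeline is testable end to end
    without clinical data, and a confusion-matrix metric suite (accuracy,
    precision, recall, specificity, F1, MCC, AUROC).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
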