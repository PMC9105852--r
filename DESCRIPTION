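Package: ToneROI
Title: Tone-Curve Correction and Shallow-CNN Evaluation for Ultrasound ROI Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Grey-level tone-curve and inverse-tone-curve correction operators
    (eight lookup-table transform types) for small B-mode ultrasound regions of
    interest, together with the experimental machinery to measure their effect
    on texture classification: a synthetic speckle ROI generator, a shallow
    convolutional neural network trained with ADAM, classical pixel-vector
    baselines (k-NN, linear SVM, LDA, random forest), and a repeated stratified
    holdout error-rate estimator with Student-t confidence intervals, parameter
    sweeps, cross-validated parameter selection and paired method comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    png,
    MASS,
    class,
    e1071,
    randomForest,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'utils.R'
    'AllGenerics.R'
    'GreyImage-class.R'
    'ToneCurve-class.R'
    'LabeledDataset-class.R'
    'synthdata.R'
    'cnn.R'
    'classifiers.R'
    'evaluate.R'
    'io.R'
    'ToneROI-package.R'
    'RcppExports.R'
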