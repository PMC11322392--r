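Package: SpeckleStrain
Title: Speckle-Tracking Deformation Analysis of Dorsal Neck Muscle Ultrasound
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies skeletal muscle deformation from B-mode ultrasound
    video by speckle tracking. Provides a synthetic speckle phantom and cohort
    simulator with exact ground-truth layer strain, a pyramidal Lucas-Kanade
    point tracker with a least-squares linear strain fit over a longitudinal
    region of interest, deformation (%) and deformation-rate (%/s) curves,
    trapezoidal curve-area statistics split at the 0% line with
    linear-interpolated crossings, and the associated inference machinery:
    mixed-design repeated-measures ANOVA with Mauchly sphericity test,
    Greenhouse-Geisser correction, partial eta-squared and Bonferroni post-hoc
    level contrasts, plus PCA and OPLS-DA with stratified leave-out-p
    cross-validation and jackknife confidence intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    tiff,
    png,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'SpeckleStrain-package.R'
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'curves.R'
    'areas.R'
    'anova.R'
    'io.R'
    'multivariate.R'
    'tracking.R'
    'synth-speckle.R'
    'synth-cohort.R'
    'pipeline.R'
    'utils.R'
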