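Package: armetry
Title: Functional Arm-Use Classification from Wrist-Worn Accelerometry
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end pipeline for classifying functional versus
    non-functional upper-extremity movements of stroke survivors from raw
    wrist-worn tri-axial accelerometry. Provides a synthetic cohort
    generator with ground-truth labels and annotator disagreement, sensor
    CSV input/output with z-axis synchronization-peak detection and
    sensor/video clock alignment, preprocessing to scaled 2-second windows
    (down-sampling to 30 Hz, left/right axis harmonization, majority-vote
    label consensus, robust median/IQR scaling), a compact convolutional
    neural network with dense layers trained with Adam, learning-rate
    plateau reduction and early stopping, SMOTE minority oversampling for
    class imbalance, intrasubject 5-fold and leave-one-subject-out
    evaluation with accuracy and per-class F1, paired train/validation
    statistics with Cohen's d, and a handcrafted-feature random-forest
    baseline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    signal,
    pracma,
    randomForest,
    yaml,
    jsonlite,
    data.table
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
LinkingTo:
    Rcpp,
    RcppArmadillo
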