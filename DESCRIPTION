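Package: qeegcpr
Title: Quantitative-EEG Prediction of Carotid Blood Flow Recovery During CPR
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for predicting the recovery of carotid blood flow (CBF)
    during cardiopulmonary resuscitation from single-channel frontal EEG
    recorded in the brief compression-free pauses before defibrillation
    attempts. Implements the full analysis pipeline for a ventricular
    fibrillation swine resuscitation protocol: a seeded synthetic VF/CPR
    session generator, EEG band-pass filtering and overlapping sub-epoch
    segmentation, twenty quantitative-EEG parameters spanning the time,
    frequency and entropy domains (burst suppression ratio, band power
    ratios and fractions, BSR-compensated spectral edge frequency,
    Shannon/Renyi/log-energy/spectral entropies, bispectral SynchFastSlow),
    CBF recovery-rate labeling at the 30 percent criterion, neighborhood
    component analysis feature ranking with Student's t-test filtering,
    SMOTE minority oversampling inside training folds, five reference
    classifiers (logistic regression, polynomial SVM, weighted k-nearest
    neighbors, random-subspace tree ensemble, multilayer perceptron), and
    pooled leave-one-animal-out evaluation with confusion-matrix metrics
    and ROC/AUC.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    signal,
    e1071,
    rpart,
    nnet,
    yaml,
    jsonlite,
    withr,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'utils.R'
    'AllClasses.R'
    'AllGenerics.R'
    'accessors.R'
    'balancing.R'
    'edf.R'
    'evaluation.R'
    'feature-set.R'
    'features.R'
    'labeling.R'
    'models.R'
    'pipeline.R'
    'preprocess.R'
    'qeegcpr-package.R'
    'reference-tables.R'
    'selection.R'
    'signal-io.R'
    'synthetic-data.R'
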