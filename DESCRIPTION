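Package: painpipe
Title: Multimodal Physiological Pain Recognition Pipeline
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end pipeline for recognizing postoperative pain from
    multimodal biosignals (ECG, facial EMG, electrodermal activity, and
    PPG-derived respiration). Provides modality-specific noise filtering,
    windowed handcrafted feature extraction (time-domain HRV, EMG amplitude
    and variability, EDA phasic decomposition by sparse nonnegative
    deconvolution, respiration via empirical mode decomposition of the PPG
    beat-amplitude envelope), convolutional and LSTM autoencoder feature
    learning, sparse-label handling through time-threshold strong labels and
    a three-classifier weak-supervision label model, SMOTE minority
    oversampling, early and late multimodal fusion, and leave-one-subject-out
    evaluation by balanced accuracy. Includes a synthetic multimodal cohort
    generator with known ground truth so every stage is testable without
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    splines,
    signal,
    yaml,
    jsonlite,
    data.table,
    e1071,
    randomForest,
    rpart
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
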