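Package: eegseizer
Title: Multi-Feature Epileptic Seizure Detection from Multi-Channel EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An automated seizure-screening pipeline for long-term
    multi-channel electroencephalography (EEG). Recordings are cleaned with
    a 50 Hz notch filter, a 0.5-40 Hz elliptic bandpass and ICA-based
    artifact rejection, segmented into 0.5 s windows, and summarised by four
    features per channel and window: the maximum of a fourth-order
    Yule-Walker autoregressive power spectral density estimate,
    histogram-based Shannon and Renyi (order 2) entropies, and the averaged
    Teager energy operator. Feature separability is screened with
    descriptive statistics and the two-sided Wilcoxon rank-sum test, and a
    single-hidden-layer perceptron trained by scaled conjugate gradient
    classifies windows as normal or ictal. Window decisions are merged into
    seizure events and scored by event sensitivity, segment specificity,
    false detections per hour and ROC/AUC. A seeded synthetic EEG generator
    (pink-noise background, alpha rhythm, 3 Hz spike-and-wave seizures,
    power-line interference and motion artifacts) makes the whole pipeline
    testable without clinical data. Includes EDF and CSV readers/writers
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC
Config/testthat/edition: 3
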