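Package: seatecg
Title: Thigh-ECG Signal Quality, Heart-Rate Variability and Biometric Identification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Analysis pipeline for single-lead electrocardiograms acquired from
    dry electrodes embedded in furniture (e.g. an instrumented toilet seat),
    recorded at the thighs simultaneously with a chest-lead reference. Provides
    a synthetic paired-session generator with controllable degradation
    (attenuation, noise, baseline wander, saturation, delayed onset), FIR
    bandpass filtering with group-delay compensation, Hamilton R-peak
    detection, per-session quality statistics (QRS detection ratio, heart-rate
    deviation, signal detection error, saturation time), heart-rate-variability
    summaries with radar-style percentage comparison, heartbeat-template
    extraction with correlation-based outlier rejection and waveform-similarity
    scoring (Pearson correlation, range-normalized RMSE), and template-based
    biometric identification with random and static train/test protocols and
    four classifiers: a binary-weight 1D convolutional neural network, linear
    one-against-all SVM, Gaussian naive Bayes and 3-nearest-neighbours.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    e1071,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    class,
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
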