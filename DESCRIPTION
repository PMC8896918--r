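Package: eegseizer
Title: Wavelet-Domain Features and Classifier Benchmarking for EEG Seizure Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects epileptic seizures in single-channel EEG segments by
    decomposing each segment into discrete-wavelet-transform subbands
    (Daubechies-4, five levels, periodized filter bank), extracting seven
    statistical and entropy features per subband (mean absolute value,
    extrema, standard deviation, average power, Shannon entropy,
    approximate entropy), and benchmarking four classical classifiers
    (linear SVM, k-nearest neighbours, Gaussian naive Bayes, decision
    tree) over a grid of two- and three-class problems with stratified
    10-fold cross-validation. Reports accuracy, sensitivity, specificity,
    predictive values and the Matthews correlation coefficient. Includes
    readers for Bonn-layout ASCII segments and clinical-style
    multichannel EDF/CSV recordings, and a seeded synthetic-EEG generator
    producing class-separable background and spike-wave segments so the
    whole pipeline is testable without any data download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    e1071,
    rpart
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
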