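Package: pcgkit
Title: Newborn Phonocardiogram Segmentation, Cycle Selection and Murmur
    Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end analysis of newborn phonocardiogram (PCG) recordings:
    Butterworth band-pass denoising of the 20-100 Hz heart-sound band, S1/S2
    detection with a complex Gaussian (Gabor) wavelet envelope, cardiac-cycle
    extraction with an interval-based systole/diastole rule, dynamic time
    warping (DTW) based selection of representative cycles for data reduction,
    time-domain and higher-order spectral feature extraction (Shannon energy,
    bispectrum, Wigner bispectrum), and linear support-vector-machine
    classification of innocent versus pathological murmurs with stratified
    k-fold cross-validation. Includes a seeded synthetic PCG simulator with
    ground-truth S1/S2 annotations so the whole pipeline is testable without
    clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    e1071,
    jsonlite,
    signal,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    pROC,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
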