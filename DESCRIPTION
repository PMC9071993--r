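Package: b2ddlpp
Title: Spatial-Spectral Feature Extraction for Motor-Imagery EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Feature extraction and classification for epoched motor-imagery
    EEG. Implements a 9-band Chebyshev type II filter bank (4-40 Hz),
    one-versus-rest filter-bank common spatial patterns (OVR-FBCSP) producing
    per-trial spatial-spectral feature matrices, graph-embedding reductions
    (LDA, 2DLDA, DLPP, 2DDLPP), and a bilinear two-dimensional discriminant
    locality preserving projection (B2DDLPP) built on a Kronecker-separable
    matrix-variate Gaussian covariance model, with eigenvalue-product feature
    ranking. Includes a synthetic ERD/ERS data generator, a stratified
    cross-validation pipeline with SVM classification, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    signal,
    e1071,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
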