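Package: bcichain
Title: Motor-Imagery and P300 EEG Decoding Chains for Brain-Computer Interfaces
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Signal-processing and decoding chains for non-invasive
    brain-computer interfaces. Implements a four-class motor-imagery
    pipeline (common average reference and surface-Laplacian spatial
    filters, a 17-feature-per-channel bank of spectral, Hjorth,
    autoregressive, fractal and entropy descriptors, and six standard
    classifiers), a P300 speller chain (post-stimulus epoching,
    Chebyshev type-I band-pass, decimation, two-phase row/column
    decoding), a finite-state-machine controller mapping four mental
    commands to application actions, and a synthetic EEG generator so
    the whole stack runs without external recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    randomForest,
    e1071,
    rpart,
    glmnet,
    class,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
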