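Package: ecgvae
Title: Variational Autoencoder for Single-Cycle ECG Generation and Feature Extraction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Encodes single cardiac cycles of an electrocardiogram (400 samples
    at 500 Hz, centered on the R peak) into 25 latent features with a
    dual-branch 1-D convolutional variational autoencoder, and generates
    synthetic cycles by decoding draws from the standard-normal prior.
    Includes a Gaussian-wave ECG simulator for fully reproducible testing,
    readers and writers for PhysioNet-style waveform records and cycle
    matrices, R-peak driven cycle extraction, Adam-based training of the
    hand-implemented network, single-feature latent traversal, and
    maximum-mean-discrepancy evaluation of generated against reference
    cycle sets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    signal,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
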