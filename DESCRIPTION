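Package: cecgclean
Title: Artifact Reduction and Binarized Entropy for Capacitive ECG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Detects and removes coarse (movement) and slow-changing
    artifacts from single-channel capacitive ECG (cECG) recordings using
    segment-wise detrended fluctuation around a linear trend, with
    data-driven thresholds and batch or online operation.  Also provides
    binarized approximate and sample entropy estimators that operate
    directly on artifact-laden signals, a synthetic cECG generator with
    ground-truth R peaks and typed artifact intervals, and segment-level
    evaluation metrics (confusion counts, SNR, R-peak retention, RR
    features, spectral band power).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
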