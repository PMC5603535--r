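Package: hetdti
Title: Drug-Target Interaction Prediction from Heterogeneous Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Predicts drug-target interactions from a heterogeneous network
    of drugs, proteins, diseases and side-effects. Each constituent network
    is diffused with random walk with restart, the per-node diffusion states
    are compressed into low-dimensional feature vectors by truncated SVD of
    the log-diffusion matrix, and a low-rank bilinear projection from drug
    feature space onto protein feature space is fitted against the known
    interaction matrix by alternating least squares. Includes a synthetic
    network generator with planted low-rank interaction structure and the
    full evaluation protocol suite: cross-validation with matched or skewed
    negative sampling, redundancy-aware test filtering, singleton-drug
    hold-outs, ranking metrics and edge-perturbation robustness checks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    jsonlite,
    methods,
    stats,
    utils,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
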