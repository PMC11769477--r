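Package: discwolf
Title: Grey Wolf Optimized Deep-Feature Classification of Lumbar Disc MRI
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Hybrid classification pipeline for binary medical-image labels
    (herniated versus non-herniated lumbar discs). Raw 12-bit image slices
    are rescaled to 8-bit and normalized, a 1024-unit fully connected head on
    a 50-layer residual backbone provides per-image deep features, a grey
    wolf optimizer learns a per-feature weight vector using wrapper
    (classifier-accuracy) fitness, and the weighted features are classified
    with a multi-layer perceptron (relu, identity, tanh or logistic
    activation) or a support vector machine (linear, rbf, sigmoid or
    polynomial kernel). Performance is reported as accuracy, precision,
    recall and F1 over stratified 5-fold cross-validation. Includes seeded
    synthetic feature and 12-bit image generators so the full pipeline is
    testable without any MRI data, plus a minimal DICOM reader and writer.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    EBImage,
    jsonlite,
    png,
    stats,
    tools,
    utils,
    yaml
Suggests:
    kernlab,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
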