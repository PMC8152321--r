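Package: tripletdr
Title: Multi-Omics Drug Response Prediction with Triplet-Loss Encoders
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Three-stage binary drug-response prediction from multi-omics
    cancer profiles (gene expression, somatic mutation, copy-number
    aberration). Each omics layer is reduced by variance-threshold feature
    selection with an elbow rule, encoded by an independently trained
    single-layer ReLU network under a batch-all triplet loss, and the frozen
    embeddings are concatenated into a single-layer sigmoid classifier
    trained with binary cross-entropy and minority oversampling. Includes
    stratified nested 5x5 cross-validation with validation-AUC
    hyperparameter selection, external validation, ablation modes, a
    label-structured multi-omics simulator, and kernel-density-based
    binarization of ln(IC50) drug sensitivity values.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
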