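Package: ktdFE
Title: Kernel Tensor Decomposition Based Unsupervised Feature Extraction for
    Multi-Omics Data
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Integrates any number of omics data blocks measured on common
    samples by stacking per-omics linear sample kernels into a single tensor,
    decomposing it with higher-order singular value decomposition (HOSVD), and
    projecting features of each block onto the biologically selected sample-mode
    singular vectors. Feature-level significance is attributed with a
    chi-squared test under a Gaussian null and Benjamini-Hochberg correction,
    which makes statistically validated feature selection possible in severe
    large-p-small-n settings. Includes a seeded synthetic benchmark with
    linear-regression, lasso and random-forest baselines, confusion-matrix
    evaluation, and an exact conditional test for cross-dataset overlap of
    selected features.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    glmnet,
    ranger,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
biocViews: Software, FeatureExtraction, DimensionReduction, StatisticalMethod
Config/testthat/edition: 3
RoxygenNote: 7.3.3
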