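Package: zetamixup
Title: Multi-Sample Mixup Augmentation with p-Series Weights
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Batch-level data augmentation that forms convex combinations of
    T >= 2 samples using weights from a randomly permuted, normalized p-series,
    generalizing pairwise mixup. Includes the pairwise mixup and Dirichlet
    mixing baselines, seeded synthetic low-dimensional manifold generators
    (crescents, spirals, helices, Gaussian blobs), a PCA-based local intrinsic
    dimensionality estimator using the Fukunaga-Olsen significant-eigenvalue
    rule, and a closed-form Bayes-oracle scorer for sample realism (prediction
    entropy) and soft-label correctness (cross-entropy).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    MASS,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
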