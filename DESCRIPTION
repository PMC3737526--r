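Package: ipcc
Title: Iterative Pearson Correlation Features for Expression-Based Class
    Discovery and Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Replaces gene-expression profiles by iteratively recomputed
    sample-sample Pearson correlation features (iPcc), an unsupervised
    feature-extraction step that sharpens latent class structure in noisy,
    high-dimensional expression matrices.  Includes a supervised additive
    batch-effect adjustment of the first-order correlation matrix, a
    simulation harness for class-structured, null and batch-confounded
    expression data, and an evaluation battery: flooring/ceiling/filter/log10
    preprocessing, F-test gene selection, repeated k-means clustering with
    optimally matched accuracy, leave-one-out Gaussian naive Bayes
    classification, intra-/inter-class similarity statistics and t-test
    comparison of accuracy distributions.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    e1071,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
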