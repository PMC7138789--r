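Package: microembed
Title: Autoencoder Representations of Microbiome Profiles for Disease
    Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Learns low-dimensional representations of high-dimensional
    microbiome profiles (strain-level presence/absence marker profiles and
    species-level relative-abundance profiles) with four autoencoder
    families -- shallow, deep, variational and convolutional -- and trains
    support vector machine, random forest and multi-layer perceptron
    classifiers on the learned representation to predict disease state.
    Model selection uses a leakage-free protocol: repeated stratified
    64/16/20 train/validation/test splits, representation learning on the
    non-test portion only, 5-fold cross-validated hyper-parameter search on
    the encoded training set, and test-set AUC/AUPRC reported as averages
    over repetitions. Includes principal-component and Gaussian
    random-projection baselines and a synthetic-profile generator with
    planted low-dimensional class structure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    jsonlite,
    optparse,
    ranger,
    stats,
    utils
Suggests:
    knitr,
    pROC,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
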