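Package: methylarg
Title: Sequence-Based Prediction and Explanation of Protein Arginine
    Methylation Sites
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts arginine methylation sites from protein primary
    sequence alone. Fixed-length peptide windows centered on arginine are
    encoded into a 434-dimensional feature vector combining amino-acid
    composition, dipeptide composition, four information-theoretic
    entropies (Shannon, Havrda-Charvat, Renyi, Arimoto) and ten
    ProtParam-style physicochemical descriptors, then classified with a
    random forest. Includes stratified k-fold and repeated
    cross-validation, an imbalance-aware train/test protocol with
    training-only under-sampling, ROC and precision-recall curves, a
    feature-block ablation runner, permutation Shapley-value attributions
    for model explanation, and a seeded synthetic-data generator with a
    plantable compositional signal for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    class,
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    ranger,
    readr,
    rlang,
    rpart,
    seqinr,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
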