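Package: ppistack
Title: Stacked Generalization for Protein-Protein Interaction Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts protein-protein interactions with a two-level stacked
    generalization ensemble (random forest, naive Bayes, neural network and
    k-nearest-neighbour base learners arbitrated by an RBF-kernel SVM) over a
    hybrid protein-pair representation: auto-covariance encodings of 14
    physicochemical amino-acid property scales, Gene Ontology term-cluster
    features indexed by the lowest common ancestors of training pairs, and
    link-prediction topology features of a Resnik-similarity-thresholded
    interaction network. Includes the matching evaluation protocol (repeated
    stratified cross-validation, MCC-maximizing decision threshold, paired
    t-tests, feature-ablation and cross-dataset drivers) and a synthetic-data
    generator so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    rlang,
    readr,
    ggplot2,
    generics,
    igraph,
    randomForest,
    e1071,
    nnet,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
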