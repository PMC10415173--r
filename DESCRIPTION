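Package: kbalance
Title: Feature-Space Balancing for k-mer Based Taxonomic Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Taxonomic classification of fixed-length DNA fragments from
    relative k-mer frequency profiles, with label-blind grid-based
    undersampling ("feature-space balancing") of the training set, simple
    ensemble classifiers (bagged decision trees, random-subspace
    k-nearest-neighbours and discriminant analysis, support vector
    machines, a single-hidden-layer neural network), macro-average
    precision evaluation, and a seeded Markov-chain simulator for
    generating labelled benchmark datasets without external downloads.
License: MIT
Encoding: UTF-8
Imports:
    Biostrings,
    class,
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    methods,
    nnet,
    purrr,
    readr,
    rlang,
    rpart,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
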