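Package: anbc
Title: Exact Learning of Augmented Naive Bayes Classifiers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Score-based exact structure learning of discrete Bayesian-network
    classifiers. Implements the BDeu marginal-likelihood score, dynamic
    programming over variable subsets for globally optimal general Bayesian
    networks and augmented naive Bayes (ANB) structures, Bayes-factor
    Markov-blanket feature selection with two-fold cross-validated
    hyperparameter tuning, expected a posteriori (EAP) parameter estimation,
    class-posterior inference restricted to the Markov blanket, and evaluation
    utilities (d-separation, Markov equivalence, CPDAG conversion, structural
    Hamming distance, class-posterior Kullback-Leibler divergence) together
    with generative sampling from discrete networks so the full stack can be
    exercised on synthetic data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
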