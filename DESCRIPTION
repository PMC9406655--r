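Package: FuzzyRankFusion
Title: Fuzzy-Rank-Based Ensemble Fusion of Classifier Decision Scores
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Late fusion of probabilistic classifier outputs for multi-class
    diagnostic problems. Implements a fuzzy-rank ensemble in which each
    classifier's softmax confidence scores are mapped to fuzzy ranks through a
    re-parameterized Gompertz function, classes outside a classifier's top-m
    most confident ranks receive penalty contributions, and the fused decision
    minimizes the product of the fuzzy-rank sum and the complement of the
    confidence-factor sum. Comparator ensembles (weighted average and the
    Sugeno fuzzy integral with a lambda-fuzzy measure built from per-classifier
    accuracies), a per-class evaluation suite (confusion matrix, precision,
    recall, specificity, F1, accuracy), a seeded Dirichlet generator of
    synthetic decision-score tensors, CSV input/output, and a command-line
    interface are included.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'scoreTensor.R'
    'gompertz.R'
    'baselines.R'
    'metrics.R'
    'synthetic.R'
    'io.R'
    'cli.R'
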