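Package: textsan
Title: Game-Theoretic Sanitization of Weakly Structured Text Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Iterative, adversary-aware redaction of sensitive tokens
    (such as personal names) from annotated text corpora. Implements the
    GreedySanitize publishing strategy, in which a publisher repeatedly
    trains a classifier on residual training data, removes its predicted
    positives, and stops once adding the classifier no longer reduces the
    publisher's expected loss. Includes a simulated budget-limited
    inspection adversary that learns a classifier from a labeled holdout
    of the published data and inspects instances predicted-positives
    first, calculators for the local-optimality characterization and the
    attacker true-positive and utility-ratio bounds (including their
    Vapnik-Chervonenkis finite-sample generalizations), a seeded
    synthetic-corpus generator with controllable sensitive-token rarity
    and surface-form ambiguity, and a cross-validated evaluation harness
    with cost-sensitive single-classifier baselines.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    glmnet,
    xgboost,
    e1071,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
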