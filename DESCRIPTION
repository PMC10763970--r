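Package: selfstack
Title: Self-Stacking and Self-Voting Random Forest Ensembles for Imbalanced Clinical Tabular Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Homogeneous stacked-generalization ("self-stacking") and self-voting
    ensemble classifiers for multi-class clinical tabular data with severe class
    imbalance, motivated by thyroid-disease screening panels. Provides a reader and
    encoder for UCI thyroid0387-style patient records, a keep-first-N down-sampling
    balancer, out-of-fold meta-feature construction for a random-forest meta-learner,
    hard/soft voting ensembles, macro-averaged one-vs-rest evaluation metrics, k-fold
    cross-validation summaries, paired t-test model comparison, and a seeded synthetic
    cohort generator emulating the thyroid dataset's class skew so the entire pipeline
    is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ranger,
    xgboost,
    nnet,
    e1071,
    rpart,
    jsonlite,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
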