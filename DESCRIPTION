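Package: rechat
Title: Predicting Recurrent Contact at a Chat-Counseling Service from
    Anonymized Conversation Text
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for predicting whether a help seeker
    will recontact a 24/7 chat-counseling service after their first
    consultation, using only privacy-preserving text representations.
    Provides sessionization of timestamped message streams by an
    inactivity gap, outcome labeling over a fixed recontact window,
    anonymization (PII token replacement, stemming, within-speaker word
    shuffling, rare-word deletion), speaker-separated TF-IDF features, a
    gradient-boosted tree classifier tuned by Bayesian search over a
    discrete hyperparameter grid, significance testing via the corrected
    5x2cv paired t-test and a label-permutation test, and a SHAP-based
    explainability layer with stem co-occurrence tables and
    embedding-based stem clustering.  A synthetic chat-corpus generator
    with calibrated message-count, word-count, and outcome distributions
    makes every stage testable without access to real counseling data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    methods,
    cluster,
    jsonlite,
    Matrix,
    randomForest,
    stats,
    utils,
    xgboost,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
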