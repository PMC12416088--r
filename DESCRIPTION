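Package: alscreen
Title: Active Learning to Rank for Collaborative Text Screening
Version: 0.1.0
Authors@R:
    person("alscreen", "developers", email = "alscreen@example.org",
           role = c("aut", "cre"))
Description: A desk-scale library for prioritized screening of text corpora
    (titles and abstracts) with active learning to rank. Provides corpus
    readers for tabular and RIS citation formats, TF-IDF and one-hot feature
    extraction, class-balanced classifiers (multinomial naive Bayes, logistic
    regression, linear SVM, bagged trees), five query strategies, ordered
    chains of ranking agents with hand-off and stopping policies, a
    deterministic discrete-event multi-annotator crowd simulator with
    worker-limited asynchronous retraining, full single-oracle simulation on
    labeled corpora, screening evaluation metrics (recall curves, WSS, ERF,
    time to discovery, normalized loss), reproducible event logging with
    replay, and a synthetic corpus generator for testing without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    data.table,
    glmnet,
    jsonlite,
    methods,
    stats,
    utils,
    withr
Suggests:
    optparse,
    readxl,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
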