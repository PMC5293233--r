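Package: mortcod
Title: Cause-of-Death Coding from Plaintext Autopsy Reports
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multi-class ICD-10 cause-of-death classification of plaintext
    autopsy reports. Implements an expert-driven feature-selection scheme in
    which per-class ranked lexicons with synonym groups are matched against
    each report to yield one frequency-count attribute per class, alongside
    five automated filter feature-ranking schemes (information gain,
    chi-square, Pearson correlation, a linear-kernel Fisher-Markov selector,
    and an information-gain/odds-ratio ensemble), an ensemble multi-filter
    rank-aggregation baseline, a uniform classifier harness (naive Bayes,
    linear SVM, k-nearest neighbour, entropy-split decision tree, random
    forest) under stratified 10-fold cross-validation, macro-averaged
    evaluation metrics with per-class Hand-and-Till AUC, and a seeded
    synthetic autopsy-report corpus generator for end-to-end benchmarking.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    foreign,
    e1071,
    caret,
    randomForest,
    rpart
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
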