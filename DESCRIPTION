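Package: flexiphys
Title: Psychophysiological Biomarkers of Mental Flexibility
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline from raw psychophysiological recordings
    (blood volume pulse, respiration, facial electromyography, skin
    conductance) to mental-flexibility group discrimination. Extracts
    heart-rate-variability indices in the time, frequency and Poincare
    domains, respiration-rate, EMG-envelope-ratio and skin-conductance
    indices; compares High- and Low-flexibility groups (median split of
    the Cognitive Flexibility Inventory) with pooled-variance t-tests and
    effect sizes, from raw data or published group summaries; ranks
    features by information gain, compares kNN, SVM, random-forest and
    naive-Bayes classifiers under leave-one-out cross-validation, and
    induces threshold decision rules. Includes generators for synthetic
    signals with known ground truth and synthetic cohorts drawn from
    group summary statistics, so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    pracma,
    nortest,
    e1071,
    randomForest,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    rpart
Config/testthat/edition: 3
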