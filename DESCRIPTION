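Package: medialearn
Title: Active-Learning Optimization of Microbial Culture Media
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Machine-learning-guided Design-Build-Test-Learn (DBTL) optimization
    of defined culture media. Provides Latin hypercube initial designs over a
    bounded concentration phase space, a probabilistic ensemble surrogate
    (Gaussian process, random forest, gradient-boosted trees, ridge) predicting
    response mean and variance, batch recommendation by maximizing an
    exploration/exploitation acquisition with differential evolution,
    Shapley-value feature attribution, a media compiler that turns designs into
    liquid-handler worklists for 48-well plates, a synthetic flaviolin-response
    simulator for full-pipeline testing, and a synthetic-function benchmark
    comparing the ensemble recommender against response-surface and plain-GP
    baselines.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lhs,
    randomForest,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
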