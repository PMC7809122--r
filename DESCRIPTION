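Package: gcml
Title: G-Computation with Machine-Learning Q-Models for Binary Exposures
    and Outcomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates the average causal effect (ACE) of a binary exposure
    on a binary outcome by G-computation (standardization). The outcome
    regression (Q-model) can be a penalized logistic regression (lasso or
    elastic-net), a single-hidden-layer neural network, a radial-kernel
    support vector machine, boosted classification trees, or an AUC-weighted
    super learner combining them. Tuning parameters are selected by
    maximising cross-validated AUC; the variance of the ACE is obtained by
    bootstrap cross-validation (training on each resample, estimating the
    effect on the out-of-bag individuals). Includes a simulation framework
    with realistic and simplistic logit-linear data-generating scenarios,
    Monte-Carlo computation of the theoretical ACE, and the standard
    performance criteria (bias, RMSE, empirical and asymptotic standard
    deviations, variance estimation bias, coverage, power).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    glmnet,
    nnet,
    kernlab,
    xgboost,
    lhs,
    splines,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
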