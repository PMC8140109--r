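Package: permfit
Title: Permutation-Based Feature Importance Tests for Black-Box Learners
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Estimates and tests per-feature importance in black-box
    regression and classification models by measuring the increase in
    held-out prediction loss after permuting one feature at a time.
    Importance scores come with standard errors, one-sided Z p-values and
    optional false-discovery-rate adjustment; cross-fitting removes the
    overfitting bias of naive plug-in permutation importance.  Ships three
    self-contained learner backends (bagged feed-forward neural networks,
    random forests, and radial-kernel support vector machines), the
    classical per-tree out-of-bag random-forest importance baseline, a
    block-correlated Gaussian simulation design for calibration studies,
    and a replication harness that reports detection rates and prediction
    error before and after feature selection.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
SystemRequirements: C++17
Config/testthat/edition: 3
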