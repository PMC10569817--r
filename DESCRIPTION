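Package: cohortbalance
Title: Distribution-Matched Undersampling and Risk-Factor Importance for
    Imbalanced Cohort Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for ranking risk-factor importance in imbalanced
    binary-outcome cohort data. Implements a best-of-M distribution-matched
    undersampler (plain and age/sex-stratified) that scores candidate
    majority-class subsamples with chi-squared goodness-of-fit and
    Kolmogorov-Smirnov tests and keeps the candidate with the highest summed
    p-values; binary logistic regression with clinical performance metrics
    (sensitivity, specificity, precision, NPV, accuracy), two-proportion
    tests and joint Wald tests for multi-level factors; variable importance
    from the flatness of partial-dependence curves; an in-package SMOTE
    oversampler for comparison; and a synthetic clinical-cohort generator
    with known ground-truth effects so the whole pipeline can be exercised
    without access-restricted trial data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
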