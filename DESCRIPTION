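Package: hsvr
Title: Hierarchical Support Vector Regression for Efflux-Ratio QSAR Modeling
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantitative structure-activity relationship (QSAR) modeling of
    the P-glycoprotein efflux ratio with a hierarchical support vector
    regression (HSVR) scheme: descriptor filtering and autoscaling,
    Kennard-Stone train/test partitioning, genetic-algorithm plus
    recursive-feature-elimination descriptor-subset selection, grid-searched
    epsilon- and nu-SVR member models with RBF kernels, a second-level SVR
    regressing the member predictions, and a complete external-validation
    battery (determination coefficients, Roy rm2 family, qF1/qF2/qF3,
    concordance correlation, Y-scrambling, and the collected stringent
    pass/fail criteria). Includes a seeded synthetic-data generator that
    emulates the descriptor intercorrelation structure and the inverted-U
    response dependencies the method is designed to capture.
License: MIT + file LICENSE
Encoding: UTF-8
RoxygenNote: 7.3.3
Imports:
    e1071,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
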