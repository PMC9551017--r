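Package: greynet
Title: Gene Regulatory Network Inference from Time Series via Dynamic
    Grey Association and Granger Regression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers directed gene regulatory networks from time-course bulk
    expression data in two stages. First, a dynamic grey association score is
    computed between every candidate regulator and each target gene by grey
    relational analysis over sliding windows whose lengths adapt to the
    information entropy of the target's expression derivative. Second,
    multivariate Granger-style regression on lagged designs (lasso, ridge,
    random forest, or gradient boosting) converts associations into directed,
    ranked regulatory edges. Includes readers and writers for DREAM4-dialect
    time-series tables and gold-standard edge lists, ranking evaluation
    (AUROC, AUPRC, precision at k), a paired-trial ablation harness with
    Wilcoxon comparison, and a synthetic benchmark generator (VAR(1) and
    Hill-kinetics dynamics on random directed networks).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    ranger,
    xgboost,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    pROC
Config/testthat/edition: 3
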