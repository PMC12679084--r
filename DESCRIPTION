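Package: mgoscav
Title: Concentration-Aware Deep Learning Screen for Methylglyoxal Scavengers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Train and benchmark a concentration-conditioned one-dimensional
    convolutional regressor of methylglyoxal (MGO) scavenging activity from
    molecular descriptor tables, validate it as a binary classifier on labeled
    compound sets (AUROC, bootstrap confidence interval, Youden cutoff), rank
    candidate scavengers over a concentration grid, and explain predictions
    with kernel Shapley values. Includes a synthetic-data generator emulating
    sparse informative descriptors driving a latent potency with a monotone
    Hill-type dose response, univariate F-test feature selection, and
    lasso/ridge/random-forest/support-vector baselines with validation-set
    hyperparameter search.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    glmnet,
    e1071,
    generics,
    jsonlite,
    purrr,
    ranger,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
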