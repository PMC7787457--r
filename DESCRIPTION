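Package: hftraj
Title: Recurrent Disease-Progression Models for Heart-Failure Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Longitudinal modelling of recurrent heart-failure
    hospitalizations (HFH) in congenital heart disease cohorts. Encodes
    patient records into six-month time steps, trains gated recurrent unit
    (GRU) trajectory models -- including a co-morbidity-augmented multi-task
    variant and an LSTM baseline -- with an alpha-weighted focal-loss
    objective, rolls risk trajectories out auto-regressively over multi-year
    horizons, and evaluates them with frequency, conservative, balanced and
    F1-optimized decision thresholds and per-year metrics. Ships a synthetic
    cohort generator emulating the marginal co-morbidity frequencies and
    recurrent-event structure of an administrative congenital heart disease
    database, so the full pipeline runs without access to protected records.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    rlang,
    readr,
    ggplot2,
    generics,
    glmnet,
    e1071,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
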