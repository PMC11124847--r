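Package: otter
Title: Analysis of Opto-Thermal Transient Emission Radiometry Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Forward models, inversion, and machine-learning benchmarking for
    opto-thermal transient emission radiometry (OTTER), a pulsed-laser
    photothermal technique used to measure skin hydration and its depth
    profile. Provides the erfc-type transient emission decay model for
    optically homogeneous samples and its closed-form extension for a linear
    absorption-coefficient depth gradient; conversions between decay
    lifetime, emission absorption coefficient, and water content; nonlinear
    least-squares parameter recovery; segmented least-squares (SLS) depth
    profiling; a seeded synthetic-signal generator emulating volunteer
    measurement campaigns; and train/test benchmarking of standard
    regression and classification estimators on raw signal features,
    including PCA/LDA embeddings and per-feature importance attribution.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    rlang,
    ggplot2,
    generics,
    minpack.lm,
    MASS,
    e1071,
    randomForest,
    rpart,
    nnet,
    glmnet,
    xgboost,
    caret,
    mixOmics,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
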