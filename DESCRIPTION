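Package: playEE
Title: Free-Living Energy Expenditure Estimation from Raw Accelerometry in Preschool Children
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A tested pipeline for estimating free-living energy expenditure (EE)
    of preschool-aged children from raw tri-axial accelerometry calibrated against
    portable indirect calorimetry. Includes a seeded synthetic-data generator for
    20-minute free-play sessions (accelerometer signals, breath-by-breath gas
    exchange, ground-truth EE), calorimetry preprocessing (10 s binning, 60 s
    moving-average smoothing, Weir conversion, Schofield resting EE, MET
    normalization), a per-window time/frequency feature catalog, minimum-redundancy
    maximum-relevance feature selection, random forest / support vector machine /
    neural network models under leave-one-subject-out cross-validation, and an
    evaluation battery (RMSE, MAPE, repeated-measures ANOVA with Fisher LSD,
    Bland-Altman agreement with proportional bias).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    signal,
    randomForest,
    e1071,
    nnet,
    data.table,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
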