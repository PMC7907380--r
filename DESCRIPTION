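Package: sentinelews
Title: Sentinel-Animal Movement Analysis for Intruder Early Warning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis pipeline for detecting and localizing
    human intruders from the collective movement responses of GPS- and
    accelerometer-collared sentinel herbivores. Provides a synthetic
    savanna world with multi-species herds and planted flight/regroup
    responses, sensor-realistic degradation of trajectories, a five-step
    trajectory reconstruction (outlier filtering, spike correction, Kalman
    smoothing, activity-informed interpolation, X-spline resampling),
    context-standardized movement feature engineering, importance-based
    feature selection with two-stage principal component reduction,
    per-animal behavioral response classification with support vector
    machines and grouped cross-validation, system-level intrusion
    detection via residualized feature ordering and logistic regression,
    and intruder localization through a wrapped-normal/lognormal
    odds-ratio probability surface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    data.table,
    zoo,
    ape,
    e1071,
    randomForest,
    yaml,
    jsonlite,
    xml2,
    rlang,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    ggplot2
Config/testthat/edition: 3
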