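Package: rkknn
Title: Random Kernel k-Nearest Neighbors Regression
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Ensemble nonparametric regression combining bootstrap
    aggregation, random feature subspaces and kernel-weighted k-nearest
    neighbor prediction (RK-KNN). Each ensemble member is fit on a bootstrap
    sample restricted to a random subset of features, with its neighbor
    count k and kernel bandwidth h selected by cross-validated grid search;
    member predictions are aggregated by the mean. Includes the plain KNN
    and random-KNN (R-KNN) baselines, six kernel weighting families
    (Gaussian, Epanechnikov, uniform, triangular, quartic, tricube),
    min-max feature scaling, RMSE/MAE/R-squared evaluation with
    competition-rank model comparison, seeded synthetic data generators,
    JSON model persistence and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
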