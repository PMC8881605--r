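Package: yieldcnn
Title: Winter Wheat Yield Modelling with Multi-Branch 1-D Convolutional Networks
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: County-year winter wheat yield prediction from weekly weather
    series, soil water-retention properties and crop phenology dates. Provides
    a synthetic county-year panel generator with a documented ground-truth
    yield response, weekly feature assembly with z-score standardisation and
    year-wise (non-random) hold-out splitting, a multi-branch 1-D convolutional
    network fused with a fully-connected branch for static features, eight
    classical baseline learners with cross-validated hyperparameter search,
    evaluation metrics (MAE, RMSE, root-of-R2 correlation, per-county
    percentage error, residual normality), Kernel SHAP interpretation (global
    importance, force-plot data, weekly weather profiles) and Shapley-ranked
    feature-selection ablations, plus a config-driven pipeline and CLI.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    glmnet,
    jsonlite,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
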