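Package: teacelm
Title: PSO-Tuned Extreme Learning Machines for Antioxidant Capacity Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Predicts Trolox equivalent antioxidant capacity (TEAC) of sprouted
    cruciferous seeds from six biochemical composition variables (total
    phenolics, inositol hexaphosphate, glucosinolates, soluble proteins,
    ascorbic acid, total tocopherols) with an extreme learning machine whose
    random hidden layer is tuned by particle swarm optimization and whose
    output weights are solved by Moore-Penrose least squares. Includes a
    calibrated synthetic-data generator with controllable feature-target
    correlation structure, min-max normalization to [-1, 1] with a 75/25
    train/test split, a five-statistic evaluation battery (R2, MRE, MSE,
    RMSE, STD), a Williams-plot applicability-domain analysis based on
    leverage and standardized residuals, and a relevancy-factor sensitivity
    analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
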