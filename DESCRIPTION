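Package: glucopred
Title: Personalized Blood Glucose Prediction from Outpatient Lifestyle Logs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates and predicts blood glucose dynamics of insulin-treated
    diabetic outpatients from lifestyle logs (meals with full nutrient
    composition, subcutaneous insulin doses, CGMS and fingerstick glucose
    readings). Couples a two-compartment (stomach-intestine) carbohydrate
    digestion model to a delay-differential glucose-insulin control model with
    per-administration subcutaneous insulin depots. Model parameters are
    personalized by brute-force grid search, a real-coded genetic algorithm and
    Nelder-Mead simplex refinement, optionally with diurnal (24-hour periodic)
    parameter profiles capturing circadian insulin sensitivity. Predictions are
    evaluated by RMSE, absolute-error summaries and Clarke Error Grid Analysis,
    with model restarts at fingerstick measurements and sliding-window
    cross-validation. Includes a virtual-patient generator with a calibrated
    CGMS noise model for validation on synthetic data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    graphics,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
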