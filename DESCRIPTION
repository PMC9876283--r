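Package: vo2val
Title: External Validation of VO2max Prediction Equations in Endurance
    Athletes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for externally validating maximal oxygen uptake (VO2max)
    prediction equations against directly measured cardiopulmonary exercise
    testing (CPET) data in endurance athletes.  Provides tabular CPET record
    handling with strict physiological invariants, reduction of
    breath-by-breath oxygen-uptake series to a 15-second averaged VO2max,
    an inclusion/exclusion pipeline with seven maximal-exertion criteria,
    standard-deviation based endurance stratification at the respiratory
    compensation point, a pluggable registry of published prediction
    equations, and a TRIPOD-style calibration engine (adjusted R-squared,
    RMSE, calibration-in-the-large, calibration slope, paired mean
    differences).  A calibrated synthetic cohort generator with injectable
    calibration defects makes every stage testable without access to the
    original clinical data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
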