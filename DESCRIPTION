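Package: lgegv
Title: Low-Glucose Eating and Glycemic Variability from Continuous
    Glucose Monitoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline linking low-glucose eating (the fraction of
    eating events whose preprandial glucose is at or below a personalized,
    fasting-derived threshold) to continuous-glucose-monitor (CGM) glycemic
    variability. Ingests CGM traces, timestamped food logs and
    anthropometrics; validates and consolidates eating events; matches
    preprandial glucose; computes a glycemic-variability battery (SD,
    CONGA, LI, J-index, LBGI/HBGI, ADRR, GRADE, MAGE, MODD, M-value);
    classifies CGM windows into low/moderate/severe variability glucotypes
    by spectral clustering; and fits week-16 minus week-0 change-score
    correlation and weight-adjusted regression models. Includes a synthetic
    two-timepoint cohort generator with a plantable eating-pattern effect
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
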