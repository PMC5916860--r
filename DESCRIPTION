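Package: riceleafdyn
Title: Dynamic Rice Leaf Phenotyping for Nitrogen Status Diagnosis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Quantifies the dynamics of rice leaf expansion and etiolation from
    scanner-style RGB leaf images and diagnoses hydroponic nitrogen supply
    levels from those dynamics. Provides a synthetic leaf-scan generator with
    exact ground truth, extraction of leaf shape (area, perimeter, etiolated
    area and degree) and color characteristics (green channel, chromatic
    coordinates, excess green/red, dark green color index), relative growth
    rates and average changing rates over 3- and 6-day intervals, growth-curve
    fitting (power, exponential, sigmoidal logistic) compared by R-squared and
    AIC, one-way ANOVA feature screening across four nitrogen treatments, and
    multi-class support-vector-machine diagnosis evaluated by leave-one-out
    cross-validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    e1071,
    minpack.lm,
    png,
    yaml,
    jsonlite,
    stats,
    tools,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
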