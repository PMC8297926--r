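Package: mrsma
Title: Neurochemical Moderation Analysis of Mathematical Achievement Across Development
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline linking MRS-derived glutamate and GABA
    concentrations to mathematical achievement from childhood to adulthood.
    Provides voxel tissue-fraction and T2 relaxation concentration corrections
    with CRLB and outlier quality control, composite achievement scoring from
    a cognitive battery, age-moderated multiple regression with
    heteroscedasticity-consistent (HC0) inference, Johnson-Neyman probing of
    continuous interactions, assumption diagnostics (Breusch-Pagan,
    Shapiro-Wilk, variance inflation factors), and a calibrated synthetic
    cohort generator so every stage is testable without participant data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    sandwich,
    lmtest,
    car
Config/testthat/edition: 3
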