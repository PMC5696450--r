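Package: cypivive
Title: Predict CYP450 Activities in Liver Microsomes and Extrapolate Hepatic Drug Clearance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for predicting cytochrome P450 (CYP) metabolic activities in
    human liver microsomes from a reduced set of measured probe-substrate
    activities, and for extrapolating in-vivo hepatic drug clearance with the
    conventional bias-corrected in-vitro-in-vivo extrapolation (CBC-IVIVE)
    well-stirred model. Includes Michaelis-Menten kinetic fitting of microsomal
    velocity data, a published registry of multiple-linear-regression
    descriptive models linking six CYP activities (CYP2A6, 2C8, 2D6, 2E1,
    3A4/5) to four measured ones (CYP1A2, 2B6, 2C9, 2C19), SPSS-style stepwise
    model fitting, fold-error accuracy statistics (AFE, IFE, 2-fold
    concordance), and a calibrated synthetic cohort generator for end-to-end
    testing without access to individual-level microsome data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    nortest,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
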