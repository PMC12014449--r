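Package: fluorisk
Title: Dietary Fluoride Bioavailability and Probabilistic Health Risk
    Assessment
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Non-carcinogenic health risk assessment for fluoride in foods
    roasted over high-fluoride coal. Computes relative bioavailability
    (RBA) from Caco-2 transwell transport assays, EPA-style average daily
    dose and hazard quotient/index point estimates, fits candidate intake
    distributions (normal, lognormal, logistic, Gumbel-max, Weibull) by
    maximum likelihood with Anderson-Darling best-fit selection, propagates
    concentration and intake uncertainty through seeded Monte Carlo
    simulation, and inverts the risk model for maximum allowable daily
    intakes with and without bioavailability correction. Includes a
    synthetic study-data generator with known ground truth so the whole
    pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    fitdistrplus,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
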