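Package: curealpha
Title: Mixture Cure Models Corrected for Excess Non-Cancer Mortality
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits mixture cure survival models for population-based cancer
    data in the relative-survival setting, including a corrected variant in
    which the non-cancer mortality of patients is a multiplicative factor
    (alpha) times the general-population mortality. Provides maximum
    likelihood estimation from individual records or grouped life tables
    (binomial likelihood with Ederer II expected survival), a cohort
    simulator covering Weibull and exponentiated-Weibull uncured survival,
    age-dependent and randomly varying alpha, and Monte-Carlo machinery to
    evaluate bias, precision and confidence-interval coverage of the
    estimators.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
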