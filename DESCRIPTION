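Package: ureanox
Title: Nitrite and Nitrous Oxide Production from Ammonium and Urea in 15N Tracer Incubations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates gross nitrite and nitrous oxide (N2O) production rates from
    15N-labelled ammonium and urea incubation time courses, including
    tracer-dilution correction by the labelled substrate fraction, binomial
    inversion of N2O isotopologue (mass 44/45/46) accumulation, design-based
    rate detection limits, N2O yields and error-propagated oxidation-rate
    ratios. Provides the cross-site correlation framework relating urea:ammonium
    oxidation-rate ratios to substrate concentration ratios (log-log fits with
    robust 2-SD outlier flagging), the ureC:amoA functional-gene coverage-ratio
    metric for ammonia-oxidising archaea, seeded synthetic-data generators that
    emulate the incubation design and cross-site structure, and validated
    readers and writers for all table schemas.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
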