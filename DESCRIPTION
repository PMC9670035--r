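Package: restpisa
Title: Residence-Time Analysis of Proteome Integral Solubility Alteration Assays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for residence-time PISA (proteome integral
    solubility alteration) experiments that estimate drug-target residence
    times from washout time courses. Extracts isobaric reporter-ion
    intensities from centroided MS2 spectra with a ppm-window rule,
    normalizes drug-treated samples to time-matched vehicle controls, tests
    solubility shifts with equal-variance t-tests, scales off-curves and fits
    an exponential decay with an asymptotic term (or a linear fall-back) to
    obtain dissociation rate constants, asymptotic bound fractions, residence
    times and areas under the curve, and combines compressed residence-time
    and dose-response readouts into a ranked target-prioritization score.
    Includes a synthetic-data generator that simulates the assumed binding
    kinetics, dose-response occupancy and lognormal measurement noise so
    every stage is testable by parameter recovery.
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
    minpack.lm,
    yaml
Suggests:
    mzR,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
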