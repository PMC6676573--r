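Package: trtselect
Title: Treatment Selection Rules from Estimated Treatment Effect Functions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Construction and evaluation of biomarker-based treatment selection
    rules built on an estimated treatment-effect function from a randomized
    controlled trial. Fits linear or quadratic treatment-marker interaction
    models by ordinary least squares, builds pointwise and simultaneous (sup-t
    or tube-formula) confidence bands for the effect function on a bounded
    marker domain, and delta-method confidence intervals for its roots, and
    turns these into four selection rules: positivity of the estimate (EST), of
    the pointwise band's lower bound (POI), of the simultaneous band's lower
    bound (SIM), and excision of root confidence intervals (CIR), each gated by
    a treatment-marker interaction pretest. Performance of a rule against a
    known scenario (expected sensitivity, specificity, overall gain, power) is
    computed by exact integration over the future-patient marker distribution,
    and a seeded simulation engine replicates whole trials across effect-size
    grids and confidence levels.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
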