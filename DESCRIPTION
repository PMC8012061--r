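Package: poolkin
Title: Vesicle Pool Kinetics from Capacitance, Amperometry and Stereology
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of large dense-core vesicle priming and fusion in
    chromaffin cells. Fits flash-evoked membrane capacitance traces with a
    two-exponential-plus-line model and with a delayed slowly-releasable-pool
    (SRP) variant, classifies kinetic components into readily and slowly
    releasable pools, fits paired-flash recovery curves under reversible
    two-pool priming models (with and without a release-site limit) and
    derives priming/depriming rate constants, computes total and docked
    vesicle numbers per cell from electron-microscopy stereology, extracts
    amperometric spike shape parameters including foot signals, and provides
    an exact two-sided Fisher test for model-selection contingency tables.
    Includes synthetic-data generators so the whole pipeline is testable
    without raw recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    deSolve,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
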