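Package: ducknutr
Title: Dynamic Energy and Protein Requirement Modelling for Meat Ducks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a dynamic factorial model for the daily metabolizable
    energy (kJ/d) and crude protein (g/d) requirements of growing meat ducks.
    The model scales maintenance by metabolic body weight (W^0.75) and growth
    by daily gain, and adds seasonal correction factors, a temperature-lag
    compensation mechanism for sustained cold spells, breed-environment
    interaction coefficients and an amino-acid balance index. Includes a
    calibration engine (damped least squares and decaying-learning-rate
    gradient descent), a seeded synthetic flock-data generator for parameter
    recovery studies, CSV flock-record input/output and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    minpack.lm,
    withr
Config/testthat/edition: 3
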