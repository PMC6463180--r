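Package: neoref
Title: Neonatal Hemoglobin and Hematocrit Reference-Range Models
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Evaluates, refits, selects and validates reference-range models
    for neonatal hemoglobin concentration (cHb, g/dL) and hematocrit (Hct, %)
    as smooth surfaces in gestational age (22-42 weeks) and postnatal age
    (0-28 days). The mean surface is a tied-coefficient bi-quadratic with five
    free parameters; the 5th and 95th percentile surfaces are constant offsets
    from the mean. Includes closed-form and Levenberg-Marquardt fitting,
    exhaustive accuracy-complexity model selection over a quadratic term
    library, validation statistics (mean absolute error, percentile-band
    coverage), a synthetic-data generator for reference grids and clinical
    cohorts, CSV/JSON input-output, and a command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    minpack.lm,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
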