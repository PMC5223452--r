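Package: raschcir
Title: One-Parameter Rasch Measurement for Continuous Item Responses
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Joint maximum-likelihood (Newton-Raphson) estimation of the
    one-parameter Rasch model for bounded continuous item responses rescaled
    to the unit interval, with INFIT/OUTFIT mean-square fit statistics,
    Wright-map and box-plot KIDMAP diagnostics, a computerized adaptive
    testing (CAT) engine with a residual-stability stopping rule, and a
    synthetic-data generator plus an independent brute-force estimation
    oracle for validation.
License: MIT
Encoding: UTF-8
Imports:
    graphics,
    grDevices,
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
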