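Package: checkrich
Title: Compare Species Richness from Semi-Structured Checklists Against
    Structured Surveys
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying how well semi-structured citizen-science
    checklists (eBird-style) recover the species richness observed by
    structured point-count surveys (Breeding Bird Survey-style).  Implements
    checklist alignment and culling filters with full attrition logging,
    the Chao1 nonparametric richness estimator with singleton diagnostics,
    relative-bias statistics against per-site reference richness, shifted
    power-function effort models fitted by Levenberg-Marquardt least squares
    with Monte-Carlo and Taylor-expansion confidence bands, and a seeded
    synthetic-data generator with known true richness so the whole pipeline
    can be exercised end to end without external data.
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
    MASS,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    minpack.lm,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
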