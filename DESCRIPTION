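Package: orbweb
Title: Orb-Web Architecture Metrics, Calibrated Synthetic Webs and
    Species Comparisons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative analysis of orb-web architecture from
    field measurement tables: derived geometric statistics (Ellipse-Hub
    capture area, vertical asymmetry, shape, adapted mean mesh height and
    their size-normalised forms), a seeded synthetic-data generator that
    emulates cave- and surface-dwelling tetragnathid spider archetypes
    (including frame-thread elimination with radii acting as mooring
    threads), and an end-to-end species-comparison workflow: morphology
    PCA, per-response linear mixed models with species as a fixed factor
    and sampling location as a random intercept, Type II Wald F tests
    with Kenward-Roger degrees of freedom, and Tukey-adjusted pairwise
    contrasts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    car,
    emmeans,
    jsonlite,
    lme4,
    pbkrtest,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
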