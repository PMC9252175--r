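Package: ttcbia
Title: Fat-Free Mass Estimation from Hand-to-Hand Bioimpedance with a
    Two-Truncated-Cones Arm Model
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for estimating whole-body fat-free mass (FFM) from
    hand-to-hand bioelectrical impedance analysis (BIA) and upper-arm
    anthropometry. Implements truncated-cone (frustum) arm volumes, the
    bioimpedance index (height squared over resistance), published
    single-cylinder (SC) and two-truncated-cones (TTC) linear FFM
    estimators, ordinary least-squares training with bootstrap
    out-of-bag evaluation across a measurement-frequency by
    electrode-position grid, Bland-Altman agreement analysis against a
    reference method, a series-conductor forward model of hand-to-hand
    resistance, and a seeded synthetic cohort generator that emulates
    the anthropometric and impedance structure of a healthy adult
    population so that every pipeline stage can be exercised without
    access to subject-level data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
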