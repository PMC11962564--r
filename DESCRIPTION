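Package: scapulometry
Title: Reliability of Scapular Landmark Digitization and 3D Scapular
    Orientation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for measurement-reliability studies of manual anatomical
    landmark positioning on scapula surface models.  Reads repeated 3D
    digitizations of the three ISB scapula landmarks (acromial angle,
    inferior angle, trigonum spinae), expresses them in an average scapula
    coordinate system, derives the 3D scapular orientation relative to a
    thorax frame through a mobile-axis YXZ Euler sequence, and quantifies
    intraobserver repeatability and interobserver reproducibility via
    crossed random-effects variance components, intraclass correlation
    coefficients, standard errors of measurement, mean absolute deviation
    and effect sizes.  Includes deterministic implementations of the
    landmark positioning strategies on edge polylines and a fully synthetic
    study generator with known ground truth for validation.
License: MIT
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    lme4,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
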