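Package: h2axdose
Title: Radiation Dose Estimation from Gamma-H2AX Focus Counts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical tools for radiation biodosimetry with the gamma-H2AX
    focus assay. Fits identity-link quasi-Poisson calibration curves to
    overdispersed focus-count data (linear, quadratic, and joint
    time-interaction models) with dispersion-corrected standard errors,
    estimates absorbed dose by inverse regression with delta-method
    uncertainty quantification, validates calibration curves against
    reference samples via quasi-Poisson prediction intervals, and falls back
    to a two-point reference curve when validation fails. Includes an
    overdispersed focus-count simulator, tabular and JSON readers/writers,
    and ggplot2 visualisations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
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
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
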