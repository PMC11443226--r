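Package: hemsim
Title: Functional-Structural Simulation of Daylily Canopies and Bud Yield
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A daily-step functional-structural plant model (FSPM) for daylily
    (Hemerocallis citrina) stands. Couples a cloud-cover-based daily solar
    radiation model and a 72+1 source discretized sky dome with a 3D canopy
    light interception tracer (deterministic projection mode and Monte Carlo
    mode), Farquhar-von Caemmerer-Berry C3 leaf photosynthesis coupled to
    Ball-Woodrow-Berry stomatal conductance and a leaf energy balance, and a
    source-sink carbon allocation scheme driven by beta growth functions.
    Includes a 36-configuration planting-scenario sweep (row pattern, row and
    plant spacing, density), dual-criterion scenario selection on bud length
    and per-hectare yield, beta-growth calibration utilities, and a partial
    least squares path modeling (PLS-PM) post-analysis of sweep output.
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
    minpack.lm,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
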