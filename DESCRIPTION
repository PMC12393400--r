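Package: wormassays
Title: Quantitative Analysis of C. elegans Plate Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying Caenorhabditis elegans behavioral plate
    assays and reporter-based neuron mapping. Predicts NaCl gradients on
    chemotaxis assay plates from a drop schedule using a point-source
    diffusion model, converts conductivity readings to concentration by
    two-point calibration, simulates run-and-tumble worm tracks with
    tunable chemotaxis gain, parses tracker-exported position tables and
    computes the per-worm mean distance to the salt peak over the final
    minute of an assay with carry-forward imputation of detection gaps,
    counts swimming thrashes from bend-angle series, scores roaming as
    distinct grid squares traversed, computes lawn-aversion ratios from
    occupancy tables, tallies co-transmitting neurons from intersectional
    driver-by-reporter expression logic, and routes group comparisons
    through a Shapiro-Wilk normality gate to parametric or nonparametric
    test families with post-hoc comparisons against a control.
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
    multcomp,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
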