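Package: osteofuzz
Title: Fuzzy-Logic Modelling of Osteogenic Differentiation Under Magnesium
    and Inflammatory Cytokine Signalling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the early and late osteogenic differentiation of
    mesenchymal stem cells in response to extracellular magnesium ions and the
    inflammatory cytokines TNF-alpha, IL-10, IL-8 and IL-1beta. A Mamdani
    fuzzy-logic controller maps the five signal concentrations to fuzzy early
    and late differentiation rates, which are scaled to physical rates,
    integrated into a cell maturity state over piecewise-constant treatment
    schedules, and mapped to the measurable markers ALP, osteocalcin and
    alizarin red staining. Includes built-in encodings of five cell-culture
    study designs, a synthetic-measurement generator for parameter-recovery
    experiments, repeated differential-evolution calibration of the 30-entry
    free-parameter registry with a half-split convergence check, and two
    sensitivity-analysis protocols (fractional-factorial +/-50 percent
    perturbations with ANOVA, and one-at-a-time +/-15 percent perturbations).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
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
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
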