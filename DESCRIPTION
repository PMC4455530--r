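Package: gcrsim
Title: Ground-Based Galactic Cosmic Ray Reference Fields and Multi-Hit
    Exposure Kinetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Designs accelerator reference fields that reproduce the charge
    and energy spectrum of galactic-cosmic-ray absorbed dose behind
    spacecraft shielding: Bethe stopping power and CSDA energy degradation
    for heavy-ion beams, polyethylene absorber depths from exponential
    extinction, per-beam fluence budgets from dose-fluence conversion, and
    fraction-by-fraction randomized delivery schedules.  A deterministic
    multi-hit Poisson kinetics model, with a per-cell Monte Carlo
    cross-check, predicts the fraction of cells receiving multiple particle
    traversals so that chronic-exposure simulations can be sized to avoid
    fluence-rate artifacts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
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
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
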