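Package: pbpke
Title: Evaporation-Coupled PBPK Modelling of Finite-Dose Dermal Absorption
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mechanistic simulation of simultaneous evaporation and dermal
    absorption of volatile chemicals under finite-dose, unoccluded in-vitro
    permeation test (Franz diffusion cell) conditions. Evaporative flux is
    driven by vapour pressure through Fickian gas-phase diffusion (with a
    legacy wind-speed mass-transfer mode), coupled to a layered-skin
    physiologically based pharmacokinetic (PBPK) model solved by the method of
    lines with a stiff ODE integrator. Includes QSPR estimation of skin
    diffusion and partition parameters with user override, a 23-chemical
    volatile reference panel, six-compartment mass-balance accounting, and an
    R-squared evaluation harness for comparing occluded (plain PBPK) and
    unoccluded (PBPK-E) predictions with observed mass balances.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    Matrix,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
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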