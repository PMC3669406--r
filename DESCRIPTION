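Package: coronadyn
Title: Kinetics of Nanoparticle-Protein Corona Formation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Mass-action modelling of hard protein corona formation on
    nanoparticles in physiological fluid. Implements the full competitive
    adsorption ODE system with surface-fraction bookkeeping, closed-form
    metastable (fast-phase) and stable (equilibrium) corona compositions, an
    exact depletion-aware equilibrium solver, a singular-perturbation reduced
    model for the slow protein-exchange phase, analytic relative-sensitivity
    formulas with numeric sweeps, and a particle-resolved Gillespie
    simulation used to validate the mean-field limit. Ships a seeded
    synthetic protein-panel generator, YAML/CSV panel I/O, tidy result
    tables with broom-style tidiers and ggplot2 autoplot methods, and a
    command-line interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
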