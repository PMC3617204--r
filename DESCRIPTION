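Package: cd4sim
Title: ODE Modeling of Cytokine-Driven CD4+ T Cell Differentiation and Plasticity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of an ordinary-differential-equation model
    of CD4+ T cell differentiation into Th1, Th2, Th17 and induced regulatory
    (iTreg) phenotypes under an external cytokine milieu. The reaction network
    (93 species, 52 reactions, 60 ODEs) couples two-chain cytokine receptor
    modules, STAT/SMAD phosphorylation cycles and mutually inhibitory master
    regulators (T-bet, GATA3, RORgt, FOXP3) with the nuclear receptor PPARg.
    The package provides Hill and mass-action kinetics, stiff time-course
    integration with a compiled right-hand side, steady states, parameter and
    dose scans, in-silico knockout and agonist-clamp protocols (including the
    Th17-to-iTreg plasticity switch), a marker-based phenotype classifier,
    finite-difference control-coefficient sensitivity analysis, particle swarm
    parameter estimation against stimulus-response calibration data, a
    synthetic calibration-data generator, and SBML import/export.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    rlang,
    stats,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
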