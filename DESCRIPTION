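Package: matesim
Title: Stochastic Moving-Boundary Simulation of Yeast Mating
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulates the mating of budding yeast cells as a stochastic
    moving-boundary problem. Each cell is represented by its own level-set
    function whose zero contour is the plasma membrane; membranes deform
    under a normal-velocity law driven by a two-stage pheromone-sensing
    polarity circuit (Gbetagamma and active Cdc42 surrogates) with integral
    feedback and multiplicative noise. Cells are coupled through
    extracellular alpha-factor, a-factor and Bar1 protease fields with
    diffusion, decay, membrane-localised secretion and background
    production. Includes the in-silico mating assays used to quantify the
    system: mating efficiency, mating discrimination, mating competition,
    projection-direction plots and Fisher's exact comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    jsonlite,
    yaml,
    stats,
    grDevices,
    graphics,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
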