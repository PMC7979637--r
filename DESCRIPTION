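Package: poroelec
Title: Coupled Poromechanics and Bioelectricity of Cell Clusters
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Finite-strain simulator for the mechanobioelectricity of a
    closely packed cell cluster. The cluster is modelled as a compressible
    hyperelastic solid network saturated by intracellular (IC) and
    extracellular (EC) solutions of water and ions. Ion transport combines
    electro-diffusion and convection, water transport combines osmosis,
    electro-osmosis and pressure-driven flow, and the two spaces exchange
    water and ions across cell membranes through aquaporins and ion
    channels. The package provides the pointwise constitutive laws
    (Onsager mobility matrices, nominal and Cauchy stress, chemical and
    electrochemical potentials), Goldman-Hodgkin-Katz and Gibbs-Donnan
    helpers, a one-dimensional axisymmetric Galerkin finite-element
    discretization with monolithic implicit (damped Newton) time
    integration, closed-form steady-state calculators for permeable and
    tight-junction-sealed cluster boundaries, and a scenario and sweep
    driver with tidy CSV export.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    ggplot2,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
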