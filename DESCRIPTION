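Package: mstbds
Title: Brownian Dynamics Simulation of Microscale Thermophoresis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Coupled simulation of microscale thermophoresis (MST): a
    nonlinear steady-state heat-conduction solver for a laser-heated
    glass/water sample chamber (Beer-Lambert volumetric source,
    temperature-dependent water conductivity, axisymmetric finite-volume
    discretisation) feeding a seeded 2D overdamped-Langevin Brownian
    dynamics engine with thermophoretic drift, plus the analysis pipeline
    that turns particle trajectories into radial depletion profiles,
    Soret-coefficient estimates, thermophoretic-force profiles and MSD
    curves. Temperature maps measured by fluorescence thermometry can be
    imported in place of the built-in solver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tools,
    Matrix,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    yaml,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
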