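Package: lagcm
Title: Euler-Lagrange Compartment Models for Stirred-Tank Fermentation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Faster-than-real-time simulation of substrate gradients and
    microbial lifelines in stirred-tank fermentors. The liquid phase is a
    network of well-mixed compartments exchanging convective and turbulent
    mass fluxes aggregated from a gridded flow field; the biomass phase is a
    population of stochastically tracked parcels carrying intracellular
    state. Includes a synthetic divergence-free stirred-tank flow generator,
    geometric compartmentization with sparse flux matrices, a continuous-time
    Markov jump parcel tracker, Monod and structured multi-pool kinetics, an
    adaptive embedded Runge-Kutta 3(2) integrator with interleaved parcel
    jumps, and mixing-time, regime and population-heterogeneity analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    methods,
    pracma,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    deSolve,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
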