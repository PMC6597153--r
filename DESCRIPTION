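Package: treefronts
Title: Reaction-Diffusion Models of Tropical Forest-Savanna Tree Cover
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for one-dimensional
    reaction-diffusion models of tropical tree cover with a fire-mediated
    positive feedback. Implements the forest model (a single bistable
    equation for forest cover) and the full forest-savanna model (savanna
    saplings, savanna adults and forest trees), their nondimensionalization,
    potential-based Maxwell-point analysis of front pinning along rainfall
    gradients, method-of-lines integration with no-flux boundaries,
    logistic and gradient-based front extraction, pseudo-arclength
    continuation of stationary fronts with linear stability analysis, and
    ensemble diagnostics for savanna-woodland bistability and
    regular/irregular vegetation cycles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    withr,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
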