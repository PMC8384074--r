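Package: ecoevosim
Title: Spatially Explicit Eco-Evolutionary Simulation on Dynamic Landscapes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A general engine for spatially explicit eco-evolutionary
    simulation of species diversification on dynamic gridded landscapes.
    Species populations disperse along connection-cost graphs, accumulate
    divergence between geographically isolated clusters until a speciation
    threshold triggers cladogenesis, evolve a temperature niche optimum by
    Brownian motion, and are regulated by niche suitability and site carrying
    capacities that may scale with available energy. The package bundles five
    case-study model configurations for studying the latitudinal diversity
    gradient, quasi-random (Sobol) parameter-space exploration, synthetic
    landscape generators, and the pattern-oriented summary statistics
    (latitudinal richness slopes and curves, beta-splitting tree imbalance,
    normalized lineage-through-time differences, range-size spectra) used to
    confront simulated output with biodiversity data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    igraph,
    ape,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
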