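Package: bvocgame
Title: Evolutionary Game Models of Plant Volatile Emission
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Models the evolution of biogenic volatile organic compound (BVOC)
    emission as a spatial public-goods game between emitting plants and
    non-emitting cheaters. Provides a stochastic, spatially explicit lattice
    simulator with Moore-neighborhood signaling and fitness-weighted seed
    dispersal, and a mean-field (random distribution) counterpart with
    closed-form equilibria, replicator dynamics and evolutionarily stable
    strategy classification. Includes experiment drivers for alpha1-alpha2
    phase diagrams, signaling- and dispersal-range comparisons, a join-count
    clustering statistic, and ggplot2 visualizations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
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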