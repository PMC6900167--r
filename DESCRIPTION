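Package: timweb
Title: Food-Web Robustness Under Trophic Interaction Modifications
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates the robustness of model food webs to targeted species
    mortality when trophic interaction modifications (TIMs) -- third species
    modulating the strength of consumer-resource interactions -- are
    represented either as full higher-order terms or as their equivalent
    fixed-coefficient pairwise non-trophic effects. Provides a niche-model
    topology generator, allometric Lotka-Volterra parameterisation, a
    Gompertz sigmoid modification function anchored at the modifier's
    equilibrium density, windowed steady-state integration, secondary
    extinction cascade experiments, and post-hoc network and regression
    metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
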