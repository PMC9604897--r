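Package: fruitnet
Title: Kinetic Modelling and Network Topology of Mushroom Fruiting-Body
    Regulation
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Construction and analysis of a multi-compartment regulatory
    and kinetic model of basidiocarp (fruiting-body) formation in
    Pleurotus (oyster mushroom).  Provides a curated fruiting-mechanism
    network with per-reaction literature annotations, automatic
    generalized-mass-action and Michaelis-Menten rate-law assignment from
    reaction structure and modifier roles, stiff ODE simulation with
    initial-condition scans, SBML/JSON/SIF/GraphML import and export, a
    seeded generator of synthetic regulatory models, and from-scratch
    directed-network topology statistics (shortest paths, betweenness,
    clustering, neighborhood connectivity) with fidelity checks against
    the published network summary.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    xml2
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
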