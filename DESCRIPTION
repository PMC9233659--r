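Package: yulelattice
Title: Coupled Yule-Furry Lattice Model of Proliferative Domain Growth
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Exact stochastic simulation and closed-form analysis of a
    one-dimensional lattice model of cell proliferation in a growing domain,
    in which marked agents (e.g. neural crest cells invading the developing
    gut) are carried along by uniformly located proliferation events. Each
    agent moves as a Yule-Furry pure-birth process, and the whole lattice is
    a coupled superposition of such processes driven by shared site-attached
    Poisson streams. The package provides an event-driven Gillespie
    simulator, the exact site-occupancy mean and variance, the geometric
    inter-agent spacing law, the hypergeometric distribution of the marked
    mass left of a site, the continuum (lattice spacing to zero) limit with
    its binomial and normal-approximation forms, law-of-large-numbers and
    central-limit descriptions of the scaled marked mass, a reference
    finite-difference solver for the second-order occupancy PDE, and a
    Monte-Carlo goodness-of-fit harness tying the simulators to the closed
    forms.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
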