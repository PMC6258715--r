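Package: mvnail
Title: Multibody Simulation of Elastic Intramedullary Nail Expansion
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Desk-scale flexible multibody simulator for elastic
    intramedullary nails of the Marchetti-Vicenzi type. Six pre-curved
    nails are modelled as lumped sphere-beam chains (corotational
    Timoshenko segments), held straight by a sliding retention ring and
    expanding into a fractured medullary canal. Contacts follow a penalty
    law with Hertz-type stiffness and cubically smoothed damping. Staged
    closure, expansion and lateral-loading scenarios are integrated with
    a stiff linearly-implicit solver, and results are validated against
    an independent geometrically nonlinear curved-beam static benchmark.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    signal,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
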