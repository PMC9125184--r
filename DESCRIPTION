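Package: munchflow
Title: Muench Phloem Transport and Two-Sink Sucrose Partitioning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates sucrose partitioning between two competing sink organs
    in a source-two-sink plant vascular system, parameterized for potato.
    Implements three nested steady-state transport models: an analytic
    sink-kinetics-only model (VK), a lumped model with sucrose-dependent
    pathway resistance (VKR), and a spatially explicit biophysical model of
    Muench pressure-driven phloem flow on a branched element mesh, optionally
    coupled to cohesion-tension xylem water transport and to SWEET/SUT
    mediated radial sucrose efflux and retrieval through the apoplast,
    including SP6A-mediated efflux mitigation. Ships scenario drivers for
    sink-strength, sink-affinity, pathway-resistance, xylem-flow and organ
    comparison experiments, partitioning and conservation diagnostics, and a
    preset catalogue.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    deSolve,
    Matrix,
    methods,
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
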