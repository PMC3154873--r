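Package: polydyn
Title: Algebraic Analysis of Discrete Dynamical Models over Finite Fields
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Represents Boolean networks, multi-valued logical models and
    probabilistic Boolean networks as polynomial dynamical systems over a
    prime finite field F_p and analyzes their dynamics algebraically.
    Steady states and limit cycles are found by solving systems of
    polynomial equations over F_p (exact elimination with unit
    propagation in the quotient ring by the field equations) rather than
    by enumerating the state space, so attractor analysis scales to
    networks far beyond exhaustive simulation. Also computes wiring
    diagrams restricted to functional edges, elementary and signed
    functional circuits, fast-path summaries for conjunctive and
    disjunctive networks, transition graphs and true steady states of
    probabilistic systems, and provides a generator for sparse random
    test networks with implanted fixed points, plain-text model file
    readers and writers, DOT emission and a small command line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
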