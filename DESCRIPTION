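Package: qubode
Title: Classical Trajectory Dynamics via QUBO-Encoded Differential Equations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Solves systems of first-order ordinary differential equations by
    discretizing them into a quadratic least-squares functional, encoding the
    unknowns in signed fixed-point binary, compiling the functional to a
    QUBO (quadratic unconstrained binary optimization) matrix, and minimizing
    it with classical annealing-style solvers (exhaustive enumeration,
    simulated annealing, greedy bit-flip descent, and restart wrappers).
    Includes the classical Hamiltonian dynamics of a Morse diatomic (H2) as
    the reference application, with analytic bound-state trajectories,
    high-accuracy numerical references, trajectory accuracy metrics, and
    finite-difference convergence experiments.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    deSolve,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
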