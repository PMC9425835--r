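Package: torusphase
Title: Cluster Synchronization of Inhibitory Neurons on 2D Torus Lattices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Phase-reduction analysis of clustered firing in two-dimensional
    networks of inhibitory neurons with periodic boundary conditions. Computes
    the limit cycle and infinitesimal phase response (adjoint) of the
    Wang-Buzsaki interneuron model, the pairwise interaction function H of the
    weakly coupled phase model, enumerates phase-locked cluster solutions on an
    m x n torus, evaluates their stability from the closed-form eigenvalues of
    the block-circulant linearization, and verifies predictions with full
    conductance-based network simulations using transient perturbation
    protocols.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
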