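#' torusphase: cluster synchronization of inhibitory neurons on 2D torus lattices
#'
#' Tools for analyzing patterns of clustered firing in two-dimensional
#' networks of weakly coupled inhibitory neurons with periodic boundaries.
#' The pipeline: compute the limit cycle and adjoint (infinitesimal phase
#' response) of a Wang-Buzsaki interneuron ([find_limit_cycle()],
#' [compute_adjoint()]); reduce pairwise synaptic coupling to an interaction
#' function H ([interaction_function()]); enumerate the constant-step
#' phase-locked cluster solutions of an m x n torus
#' ([enumerate_solutions()]); classify their stability from the closed-form
#' block-circulant eigenvalues ([eigen_real_parts()], [classify()],
#' [stability_table()]); and verify predictions in the full conductance-based
#' network with perturb-and-relax simulations ([simulate_biophysical()],
#' [is_empirically_stable()]).
#'
#' @keywords internal
"_PACKAGE"
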