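#' Tabulated interaction function
#'
#' Container for a 2pi-periodic function tabulated on a uniform phase grid,
#' used for the interaction function H of the phase model and everything
#' derived from it (odd part, derivatives).
#'
#' @param phi uniform phase grid in `[0, 2pi)` (checked)
#' @param value function values at `phi`
#' @param provenance character note on where the table came from
#' @return an object of class `interaction_fn`
#' @export
interaction_fn <- function(phi, value, provenance = "unknown") {
  stopifnot(length(phi) == length(value), length(phi) >= 4,
            all(is.finite(value)))
  n <- length(phi)
  target <- 2 * pi * (0:(n - 1)) / n
  if (max(abs(phi - target)) > 1e-8 * 2 * pi)
    stop("phase grid must be uniform on [0, 2pi) starting at 0")
  structure(list(phi = target, value = as.numeric(value), n_grid = n,
                 provenance = provenance),
            class = "interaction_fn")
}

#' @export
print.interaction_fn <- function(x, ...) {
  cat(sprintf("interaction function: %d-point grid, range [%.4g, %.4g] (%s)\n",
              x$n_grid, min(x$value), max(x$value), x$provenance))
  invisible(x)
}

#' Evaluate a tabulated interaction function
#'
#' Periodic linear interpolation between grid points; `psi` is reduced
#' mod 2pi.
#'
#' @param H an [interaction_fn()]
#' @param psi numeric vector of phases (rad)
#' @return numeric vector of values
#' @export
if_eval <- function(H, psi) {
  n <- H$n_grid
  d <- 2 * pi / n
  x <- (psi %% (2 * pi)) / d
  i0 <- floor(x)
  w <- x - i0
  v <- H$value
  v[(i0 %% n) + 1] * (1 - w) + v[((i0 + 1) %% n) + 1] * w
}

#' Per-unit-weight synaptic coupling field
#'
#' The coupling vector field G entering the interaction-function integral:
#' only the voltage component is nonzero,
#' `G_V = -(1/C) (V_post - V_syn) s_pre`. The synaptic conductance `g_syn`
#' plays the role of the small coupling parameter epsilon of the phase model
#' and is deliberately NOT included here, so H is independent of `g_syn`.
#'
#' @param post postsynaptic state `c(V, h, n, s)`
#' @param pre presynaptic state `c(V, h, n, s)`
#' @param params a [wb_params()]
#' @return length-4 coupling vector
#' @export
synaptic_coupling <- function(post, pre, params = wb_params()) {
  c(V = -(post[[1]] - params$V_syn) * pre[[4]] / params$C,
    h = 0, n = 0, s = 0)
}

#' Interaction function of the phase model
#'
#' Computes `H(psi) = (1/T) integral_0^T Z(t) . G[X(t), X(t + psi/Omega)] dt`
#' on the limit cycle's phase grid, with the trapezoid rule for the periodic
#' integrand (on a uniform periodic grid this is the grid mean). The argument
#' of H is the presynaptic phase minus the postsynaptic phase. The coupling
#' field G is [synaptic_coupling()] for the Wang-Buzsaki cell.
#'
#' @param lc a [limit_cycle()] with the adjoint computed
#' @return an [interaction_fn()] on the same grid
#' @export
interaction_function <- function(lc) {
  stopifnot(inherits(lc, "limit_cycle"))
  if (is.null(lc$Z)) stop("limit cycle has no adjoint; run compute_adjoint()")
  N <- lc$n_grid
  params <- lc$params
  if (is.null(params)) params <- wb_params()
  # Z_V(t_i) * G_V at shift k: the phase grid and time grid coincide, so the
  # presynaptic gating variable is a circular shift of the s column.
  a <- lc$Z[, 1] * (-(lc$orbit[, 1] - params$V_syn) / params$C)
  s <- lc$orbit[, 4]
  idx <- 0:(N - 1)
  H <- vapply(idx, function(k) mean(a * s[((idx + k) %% N) + 1]), 0)
  interaction_fn(2 * pi * idx / N, H, provenance = "phase reduction")
}

#' Odd part of an interaction function
#'
#' `H_odd(psi) = (H(psi) - H(2pi - psi)) / 2`, computed grid-exactly by index
#' reversal (`psi = 0` maps to itself).
#'
#' @param H an [interaction_fn()]
#' @return an [interaction_fn()]
#' @export
odd_part <- function(H) {
  n <- H$n_grid
  rev_idx <- c(1, n:2)
  interaction_fn(H$phi, (H$value - H$value[rev_idx]) / 2,
                 provenance = paste0("odd part of ", H$provenance))
}

#' Derivative of a tabulated interaction function
#'
#' Central finite differences with periodic wraparound:
#' `H'(psi_k) = (H(psi_{k+1}) - H(psi_{k-1})) / (2 dpsi)`.
#'
#' @param H an [interaction_fn()]
#' @return an [interaction_fn()]
#' @export
if_derivative <- function(H) {
  n <- H$n_grid
  v <- H$value
  d <- (v[c(2:n, 1)] - v[c(n, 1:(n - 1))]) / (2 * (2 * pi / n))
  interaction_fn(H$phi, d, provenance = paste0("derivative of ", H$provenance))
}

#' Zero crossings of a tabulated function
#'
#' Phases in `[0, 2pi)` where the tabulated function changes sign, located by
#' linear interpolation between adjacent grid points (periodic wrap included).
#' Exact zeros on grid points are reported at the grid point.
#'
#' @param f an [interaction_fn()]
#' @return sorted numeric vector of crossing phases
#' @export
zero_crossings <- function(f) {
  n <- f$n_grid
  v <- f$value
  d <- 2 * pi / n
  out <- numeric(0)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    a <- v[i]; b <- v[j]
    if (a == 0) out <- c(out, f$phi[i])
    else if (a * b < 0) out <- c(out, f$phi[i] + d * a / (a - b))
  }
  sort(unique(out %% (2 * pi)))
}

#' Save / load an interaction function as CSV
#'
#' Two-column CSV `(phase, value)` with header; the round trip is exact on
#' the grid. Loading validates that the grid is uniform, starts at 0 and
#' covers one full period.
#'
#' @param H an [interaction_fn()]
#' @param path file path
#' @return `save_interaction_function` returns `path` invisibly;
#'   `load_interaction_function` returns an [interaction_fn()]
#' @export
save_interaction_function <- function(H, path) {
  utils::write.csv(data.frame(phase = H$phi, value = H$value), path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname save_interaction_function
#' @export
load_interaction_function <- function(path) {
  tab <- utils::read.csv(path)
  if (ncol(tab) < 2) stop("expected a two-column (phase, value) file")
  phi <- tab[[1]]
  if (anyDuplicated(phi)) stop("duplicated phase values in file")
  o <- order(phi)
  interaction_fn(phi[o], tab[[2]][o],
                 provenance = paste0("file: ", basename(path)))
}

#' Analytic interaction-function fixtures
#'
#' Tabulated analytic functions used by tests and examples so that the
#' stability machinery can be exercised without running the ODE pipeline:
#' `sin` (synchronizing coupling), `msin` (-sin, desynchronizing), and
#' `two_harmonic`, `-sin(psi) + 0.25 sin(2 psi)`, whose odd-part derivative
#' is negative at 0 and positive at pi like the biophysically derived H.
#'
#' @param n_grid grid size
#' @return named list of [interaction_fn()] objects
#' @export
analytic_fixtures <- function(n_grid = 1024) {
  phi <- 2 * pi * (0:(n_grid - 1)) / n_grid
  list(sin = interaction_fn(phi, sin(phi), "analytic: sin"),
       msin = interaction_fn(phi, -sin(phi), "analytic: -sin"),
       two_harmonic = interaction_fn(phi, -sin(phi) + 0.25 * sin(2 * phi),
                                     "analytic: -sin + 0.25 sin 2x"))
}
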