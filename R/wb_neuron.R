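#' Wang-Buzsaki interneuron parameters
#'
#' Parameter set for the conductance-based Wang-Buzsaki inhibitory interneuron
#' (fast sodium, delayed-rectifier potassium, leak, first-order inhibitory
#' synapse). Defaults are the standard values used throughout the package.
#'
#' @param C membrane capacitance (uF/cm^2)
#' @param I_app applied current (uA/cm^2); the default drives tonic firing
#' @param g_Na,g_K,g_L,g_syn maximal conductances (mS/cm^2)
#' @param V_Na,V_K,V_L,V_syn reversal potentials (mV)
#' @param gamma dimensionless temperature-like scale on the h and n kinetics
#' @param alpha0 synaptic maximal activation rate (1/ms)
#' @param tau_inh synaptic decay time constant (ms)
#' @return an object of class `wb_params`
#' @export
wb_params <- function(C = 1, I_app = 0.4, g_Na = 35, g_K = 9, g_L = 0.1,
                      g_syn = 0.05, V_Na = 55, V_K = -90, V_L = -65,
                      V_syn = -75, gamma = 1, alpha0 = 4, tau_inh = 2) {
  stopifnot(C > 0, tau_inh > 0,
            g_Na >= 0, g_K >= 0, g_L >= 0, g_syn >= 0)
  structure(list(C = C, I_app = I_app, g_Na = g_Na, g_K = g_K, g_L = g_L,
                 g_syn = g_syn, V_Na = V_Na, V_K = V_K, V_L = V_L,
                 V_syn = V_syn, gamma = gamma, alpha0 = alpha0,
                 tau_inh = tau_inh),
            class = "wb_params")
}

#' @export
print.wb_params <- function(x, ...) {
  cat("Wang-Buzsaki interneuron parameters\n")
  cat(sprintf("  I_app = %g uA/cm^2, g_syn = %g mS/cm^2, gamma = %g\n",
              x$I_app, x$g_syn, x$gamma))
  cat(sprintf("  g_Na/g_K/g_L = %g/%g/%g mS/cm^2, V_syn = %g mV\n",
              x$g_Na, x$g_K, x$g_L, x$V_syn))
  invisible(x)
}

# x/(1 - exp(-x)) with the removable singularity at x = 0 handled by series.
# Used by the sodium activation and potassium activation rate functions.
xexpm1 <- function(x) {
  out <- x / -expm1(-x)
  small <- abs(x) < 1e-7
  if (any(small)) out[small] <- 1 + x[small] / 2 + x[small]^2 / 12
  out
}

# derivative of x/(1 - exp(-x))
xexpm1_prime <- function(x) {
  small <- abs(x) < 1e-5
  out <- numeric(length(x))
  xs <- x[!small]
  if (length(xs)) {
    em <- -expm1(-xs)           # 1 - e^-x
    out[!small] <- (em - xs * exp(-xs)) / em^2
  }
  if (any(small)) out[small] <- 0.5 + x[small] / 6
  out
}

# Voltage-dependent rate functions (1/ms). Vectorized over V.
wb_rates <- function(V) {
  list(a_m = xexpm1(0.1 * (V + 35)),
       b_m = 4 * exp(-(V + 60) / 18),
       a_h = 0.07 * exp(-(V + 58) / 20),
       b_h = 1 / (exp(-0.1 * (V + 28)) + 1),
       a_n = 0.1 * xexpm1(0.1 * (V + 34)),
       b_n = 0.125 * exp(-(V + 44) / 80))
}

#' Single-cell Wang-Buzsaki right-hand side
#'
#' Time derivatives of the state `(V, h, n, s)` of one cell.
#' `synaptic_drive` is the summed presynaptic gating input
#' `sum_j W_ij s_j`; the synaptic current is
#' `g_syn * (V - V_syn) * synaptic_drive`. An isolated cell has drive 0.
#'
#' @param state numeric vector `c(V, h, n, s)` (named or positional)
#' @param params a [wb_params()] object
#' @param synaptic_drive nonnegative scalar, summed weighted presynaptic gating
#' @return numeric vector of derivatives `c(V, h, n, s)` per ms
#' @export
wb_derivatives <- function(state, params = wb_params(), synaptic_drive = 0) {
  if (!all(is.finite(state))) stop("non-finite state")
  V <- state[[1]]; h <- state[[2]]; n <- state[[3]]; s <- state[[4]]
  r <- wb_rates(V)
  m_inf <- r$a_m / (r$a_m + r$b_m)
  I_Na <- params$g_Na * m_inf^3 * h * (V - params$V_Na)
  I_K <- params$g_K * n^4 * (V - params$V_K)
  I_L <- params$g_L * (V - params$V_L)
  I_syn <- params$g_syn * (V - params$V_syn) * synaptic_drive
  a_inh <- params$alpha0 / (1 + exp(-V / 5))
  c(V = (params$I_app - I_Na - I_K - I_L - I_syn) / params$C,
    h = params$gamma * (r$a_h * (1 - h) - r$b_h * h),
    n = params$gamma * (r$a_n * (1 - n) - r$b_n * n),
    s = -s / params$tau_inh + a_inh * (1 - s))
}

#' Analytic Jacobian of the single-cell vector field
#'
#' 4x4 Jacobian of [wb_derivatives()] with respect to `(V, h, n, s)` at zero
#' synaptic drive. The s-equation is part of the single-cell system, so the
#' fourth row/column is included.
#'
#' @inheritParams wb_derivatives
#' @return a 4x4 numeric matrix
#' @export
wb_jacobian <- function(state, params = wb_params()) {
  V <- state[[1]]; h <- state[[2]]; n <- state[[3]]; s <- state[[4]]
  r <- wb_rates(V)
  da_m <- 0.1 * xexpm1_prime(0.1 * (V + 35))
  db_m <- -r$b_m / 18
  da_h <- -r$a_h / 20
  db_h <- 0.1 * r$b_h * (1 - r$b_h)
  da_n <- 0.01 * xexpm1_prime(0.1 * (V + 34))
  db_n <- -r$b_n / 80
  m_inf <- r$a_m / (r$a_m + r$b_m)
  dm_inf <- (da_m * r$b_m - r$a_m * db_m) / (r$a_m + r$b_m)^2
  sig <- 1 / (1 + exp(-V / 5))
  a_inh <- params$alpha0 * sig
  da_inh <- params$alpha0 * sig * (1 - sig) / 5
  J <- matrix(0, 4, 4, dimnames = list(c("V", "h", "n", "s"),
                                       c("V", "h", "n", "s")))
  J[1, 1] <- (-params$g_Na * h *
                (3 * m_inf^2 * dm_inf * (V - params$V_Na) + m_inf^3) -
                params$g_K * n^4 - params$g_L) / params$C
  J[1, 2] <- -params$g_Na * m_inf^3 * (V - params$V_Na) / params$C
  J[1, 3] <- -4 * params$g_K * n^3 * (V - params$V_K) / params$C
  J[2, 1] <- params$gamma * (da_h * (1 - h) - db_h * h)
  J[2, 2] <- -params$gamma * (r$a_h + r$b_h)
  J[3, 1] <- params$gamma * (da_n * (1 - n) - db_n * n)
  J[3, 3] <- -params$gamma * (r$a_n + r$b_n)
  J[4, 1] <- da_inh * (1 - s)
  J[4, 4] <- -1 / params$tau_inh - a_inh
  J
}

#' Construct a limit-cycle object
#'
#' Low-level constructor holding a phase-sampled periodic orbit together with
#' the vector field that generated it. Mostly used internally by
#' [find_limit_cycle()]; exposed so that analytic toy oscillators can be fed
#' to [compute_adjoint()] and [interaction_function()] in tests and examples.
#'
#' @param period period T (ms)
#' @param orbit N x k matrix of orbit samples at N uniform phases in `[0, 2pi)`
#' @param rhs function(y) returning the k derivatives of the isolated system
#' @param jac function(y) returning the k x k Jacobian of `rhs`
#' @param params optional parameter object (metadata)
#' @param Z optional N x k matrix of adjoint samples on the same phase grid
#' @param diagnostics optional list of convergence diagnostics
#' @return an object of class `limit_cycle`
#' @export
limit_cycle <- function(period, orbit, rhs, jac, params = NULL, Z = NULL,
                        diagnostics = list()) {
  orbit <- as.matrix(orbit)
  n_grid <- nrow(orbit)
  structure(list(T = period, omega = 2 * pi / period,
                 phi = 2 * pi * (0:(n_grid - 1)) / n_grid,
                 orbit = orbit, Z = Z, rhs = rhs, jac = jac,
                 params = params, n_grid = n_grid,
                 diagnostics = diagnostics),
            class = "limit_cycle")
}

#' @export
print.limit_cycle <- function(x, ...) {
  cat(sprintf("limit cycle: T = %.6g ms (%.3g Hz), %d phase samples, adjoint %s\n",
              x$T, 1000 / x$T, x$n_grid,
              if (is.null(x$Z)) "not computed" else "computed"))
  invisible(x)
}

# Integrate the single-cell system; thin deSolve wrapper.
wb_integrate <- function(y0, times, params, rtol = 1e-8, atol = 1e-10) {
  f <- function(t, y, p) list(wb_derivatives(y, p))
  deSolve::ode(y0, times, f, params, method = "lsoda",
               rtol = rtol, atol = atol, maxsteps = 100000)
}

# From state y (assumed near/on the attractor), integrate to the next upward
# V = 0 crossing and polish the crossing time by Newton iteration on V(t).
# Returns list(t = crossing time, y = state exactly at the crossing).
# refractory: V must first drop below -20 mV before a crossing is accepted,
# so a start exactly on the section is not re-detected at t = 0.
wb_next_crossing <- function(y, params, t_max = 400, dt_scan = 0.05,
                             rtol = 1e-10, atol = 1e-12) {
  tt <- seq(0, t_max, by = dt_scan)
  o <- wb_integrate(y, tt, params, rtol, atol)
  V <- o[, 2]
  armed <- cumsum(V < -20) > 0
  up <- which(V[-length(V)] < 0 & V[-1] >= 0 & armed[-length(V)])
  if (!length(up)) return(NULL)
  i <- up[1]
  t_star <- tt[i]
  y_star <- o[i, -1]
  for (k in 1:6) {
    dV <- wb_derivatives(y_star, params)[[1]]
    dt <- -y_star[[1]] / dV
    o2 <- wb_integrate(y_star, c(0, dt), params, 1e-12, 1e-14)
    y_star <- o2[2, -1]
    t_star <- t_star + dt
    if (abs(y_star[[1]]) < 1e-12) break
  }
  list(t = t_star, y = y_star)
}

#' Find the periodic firing orbit of a Wang-Buzsaki cell
#'
#' Integrates the isolated cell from a generic initial state, discards a
#' transient, and locates the stable periodic orbit with a Poincare section at
#' the upward crossing of V = 0 mV (phase origin). The section return map is
#' iterated, with Newton refinement of each crossing time, until the period
#' and section state converge; the orbit is then resampled at `n_grid` uniform
#' phases.
#'
#' @param params a [wb_params()] object; `I_app` must be above the firing
#'   threshold
#' @param n_grid number of uniform phase samples (default 1024)
#' @param tol relative agreement required between successive return times
#' @param t_transient transient discarded before period detection (ms)
#' @param t_max maximum additional time to search for a first spike (ms)
#' @param y0 initial state `c(V, h, n, s)` (the default is a generic
#'   subthreshold state; the attracting orbit is unique, so any state in its
#'   basin gives the same result)
#' @return a [limit_cycle()] object (adjoint slot empty; see
#'   [compute_adjoint()])
#' @examples
#' \donttest{
#' lc <- find_limit_cycle(wb_params(), n_grid = 256)
#' lc$T
#' }
#' @export
find_limit_cycle <- function(params = wb_params(), n_grid = 1024,
                             tol = 1e-8, t_transient = 1500, t_max = 2000,
                             y0 = c(V = -64, h = 0.78, n = 0.09, s = 0)) {
  tr <- wb_integrate(y0, c(0, t_transient), params)
  y <- tr[2, -1]
  cr <- wb_next_crossing(y, params, t_max = t_max)
  if (is.null(cr)) stop("no oscillation: no upward V = 0 crossing found")
  y <- cr$y
  T_prev <- NA_real_
  isi_rel <- NA_real_
  for (it in 1:20) {
    cr <- wb_next_crossing(y, params)
    if (is.null(cr)) stop("no oscillation: firing stopped during refinement")
    step <- max(abs(cr$y - y))
    y <- cr$y
    if (!is.na(T_prev)) isi_rel <- abs(cr$t - T_prev) / cr$t
    T_prev <- cr$t
    if (!is.na(isi_rel) && isi_rel < tol && step < 1e-9) break
  }
  if (is.na(isi_rel) || isi_rel > tol)
    stop(sprintf("period did not converge (relative change %.2e)", isi_rel))
  period <- T_prev
  tg <- (0:(n_grid - 1)) * period / n_grid
  orb <- wb_integrate(y, c(tg, period), params, 1e-10, 1e-12)
  resid <- max(abs(orb[n_grid + 1, -1] - orb[1, -1]))
  orbit <- orb[1:n_grid, -1, drop = FALSE]
  colnames(orbit) <- c("V", "h", "n", "s")
  limit_cycle(period, orbit,
              rhs = function(y) wb_derivatives(y, params),
              jac = function(y) wb_jacobian(y, params),
              params = params,
              diagnostics = list(section_residual = abs(y[[1]]),
                                 isi_rel_change = isi_rel,
                                 periodicity_residual = resid))
}

# Periodic cubic interpolant of the orbit: function(t) -> k-vector
orbit_interpolant <- function(lc) {
  tg <- lc$phi / lc$omega
  k <- ncol(lc$orbit)
  sp <- lapply(seq_len(k), function(j)
    stats::splinefun(c(tg, lc$T), c(lc$orbit[, j], lc$orbit[1, j]),
                     method = "periodic"))
  function(t) {
    tm <- t %% lc$T
    vapply(sp, function(f) f(tm), 0)
  }
}

#' Compute the adjoint (infinitesimal phase response) of a limit cycle
#'
#' Solves the linearized adjoint system `dZ/dt = -DF(X(t))^T Z` by backward
#' integration over repeated periods; directions that are stable forward in
#' time decay backward, leaving the unique periodic adjoint. Iteration stops
#' when the period-to-period change of the (normalized) adjoint is below
#' `tol`. The converged adjoint is rescaled so that the period average of
#' `Z(t) . F(X(t))` equals 1.
#'
#' @param lc a [limit_cycle()] with `rhs` and `jac`
#' @param tol relative sup-norm change between consecutive periods
#' @param max_periods maximum number of backward periods
#' @return `lc` with the `Z` slot filled and an `adjoint_residual` diagnostic
#' @export
compute_adjoint <- function(lc, tol = 1e-7, max_periods = 60) {
  stopifnot(inherits(lc, "limit_cycle"))
  N <- lc$n_grid
  k <- ncol(lc$orbit)
  Xof <- orbit_interpolant(lc)
  Fg <- t(apply(lc$orbit, 1, lc$rhs))
  if (k == 1) Fg <- matrix(Fg, ncol = 1)
  # backward time: tau measured from the end of the block; t = T - tau
  arhs <- function(tau, Z, p) {
    J <- lc$jac(Xof((lc$T - tau) %% lc$T))
    list(as.vector(t(J) %*% Z))
  }
  taug <- seq(0, lc$T, length.out = N + 1)
  Z <- c(1, rep(0, k - 1))
  norm_block <- function(zmat) {
    # rows tau = 0..T  ->  t = T..0; reorder to t = 0, T/N, ..., phase grid
    zz <- zmat[rev(seq_len(N + 1)), , drop = FALSE][1:N, , drop = FALSE]
    K <- mean(rowSums(zz * Fg))
    list(z = zz / K, K = K)
  }
  prev <- NULL
  resid <- Inf
  for (p in seq_len(max_periods)) {
    sol <- deSolve::ode(Z, taug, arhs, NULL, method = "lsoda",
                        rtol = 1e-10, atol = 1e-12)
    Z <- sol[N + 1, -1]
    nb <- norm_block(sol[, -1, drop = FALSE])
    if (!is.null(prev)) {
      resid <- max(abs(nb$z - prev)) / max(abs(nb$z))
      if (resid < tol) {
        lc$Z <- nb$z
        colnames(lc$Z) <- colnames(lc$orbit)
        lc$diagnostics$adjoint_residual <- resid
        lc$diagnostics$adjoint_periods <- p
        return(lc)
      }
    }
    prev <- nb$z
    Z <- Z / max(abs(Z))  # keep magnitude bounded across blocks
  }
  stop(sprintf("adjoint did not converge after %d periods (residual %.2e)",
               max_periods, resid))
}

#' Write / read a limit cycle as plain-text tables
#'
#' The orbit and adjoint are written as two CSV tables
#' `(phase, V, h, n, s)` and `(phase, Z_V, Z_h, Z_n, Z_s)`, with a JSON
#' sidecar holding the period, frequency and parameters. `read_limit_cycle`
#' restores an object usable by all downstream phase-model analysis (the
#' `rhs`/`jac` closures are rebuilt from the stored parameters).
#'
#' @param lc a [limit_cycle()]
#' @param path base path; files `<path>_orbit.csv`, `<path>_adjoint.csv`,
#'   `<path>.json` are written
#' @return `write_limit_cycle` returns `path` invisibly; `read_limit_cycle`
#'   returns a `limit_cycle`
#' @export
write_limit_cycle <- function(lc, path) {
  utils::write.csv(data.frame(phase = lc$phi, lc$orbit),
                   paste0(path, "_orbit.csv"), row.names = FALSE)
  if (!is.null(lc$Z)) {
    zt <- data.frame(phase = lc$phi, lc$Z)
    names(zt) <- c("phase", paste0("Z_", colnames(lc$orbit)))
    utils::write.csv(zt, paste0(path, "_adjoint.csv"), row.names = FALSE)
  }
  meta <- list(T = lc$T, omega = lc$omega, n_grid = lc$n_grid,
               params = unclass(lc$params), diagnostics = lc$diagnostics)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_limit_cycle
#' @export
read_limit_cycle <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  orb <- utils::read.csv(paste0(path, "_orbit.csv"))
  params <- do.call(wb_params, as.list(meta$params))
  Z <- NULL
  zfile <- paste0(path, "_adjoint.csv")
  if (file.exists(zfile)) {
    zt <- utils::read.csv(zfile)
    Z <- as.matrix(zt[, -1])
    colnames(Z) <- sub("^Z_", "", colnames(Z))
  }
  lc <- limit_cycle(meta$T, as.matrix(orb[, -1]),
                    rhs = function(y) wb_derivatives(y, params),
                    jac = function(y) wb_jacobian(y, params),
                    params = params, Z = Z,
                    diagnostics = as.list(meta$diagnostics))
  lc
}
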