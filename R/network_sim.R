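#' Build the network connectivity matrix
#'
#' Dense N x N nonnegative weight matrix over the row-major site order: entry
#' (site, neighbor) holds the stencil weight of the offset joining them, with
#' torus wraparound. Offsets that coincide on small lattices (e.g. +2 and -2
#' horizontally when n = 4) are summed into the same entry; a warning is
#' issued since the effective neighbor count then drops.
#'
#' @param lat a [torus_lattice()]
#' @param w a [coupling_weights()]
#' @return N x N matrix of class `connectivity` with `lattice` and `weights`
#'   attributes
#' @export
build_connectivity <- function(lat, w) {
  stopifnot(inherits(lat, "torus_lattice"), inherits(w, "coupling_weights"))
  S <- w$offsets
  N <- lat$N
  W <- matrix(0, N, N)
  coincide <- FALSE
  for (j in 0:(lat$m - 1)) {
    for (i in 0:(lat$n - 1)) {
      row <- site_index(i, j, lat)
      for (r in seq_len(nrow(S))) {
        if (w$w[r] == 0) next
        col <- site_index(i + S[r, 1], j + S[r, 2], lat)
        if (W[row, col] > 0) coincide <- TRUE
        W[row, col] <- W[row, col] + w$w[r]
      }
    }
  }
  diag(W) <- 0
  if (coincide)
    warning("stencil offsets coincide on this lattice; weights summed")
  structure(W, class = c("connectivity", "matrix"),
            lattice = lat, weights = w)
}

#' Alternating-phase 4-cluster template
#'
#' The 4-cluster pattern observed in simulations in which the horizontal and
#' vertical phase steps alternate between +pi/2 and -pi/2 between neighboring
#' cells (it is not a constant-step solution). Cells at (even column, even
#' row) have phase 0; the firing order advances by quarter periods around
#' each 2 x 2 block. On a 4 x 4 lattice the four clusters are the row-major
#' cell sets {1,3,9,11}, {2,4,10,12}, {6,8,14,16}, {5,7,13,15}.
#'
#' @param lat a [torus_lattice()] with even m and n
#' @return a `phase_field` matrix
#' @export
alternating_phase_field <- function(lat) {
  stopifnot(lat$m %% 2 == 0, lat$n %% 2 == 0)
  i <- 0:(lat$n - 1)
  j <- 0:(lat$m - 1)
  f <- outer(j, i, function(jj, ii)
    ifelse(jj %% 2 == 0, (ii %% 2) * pi / 2, pi + ((ii + 1) %% 2) * pi / 2))
  structure(f, class = c("phase_field", "matrix"))
}

#' Initialize network states on a phase pattern
#'
#' Places each cell on the single-cell limit cycle at its pattern phase
#' (periodic interpolation of the orbit), so the network starts exactly on
#' the intended cluster solution. `pattern` may be a phase-field matrix or
#' the named template `"alternating"` (see [alternating_phase_field()]).
#'
#' @param pattern an m x n phase matrix or `"alternating"`
#' @param lc a [limit_cycle()]
#' @param lat a [torus_lattice()]; required when `pattern` is a template name
#' @return N x 4 matrix of per-site states `(V, h, n, s)` in row-major site
#'   order
#' @export
init_from_pattern <- function(pattern, lc, lat = NULL) {
  stopifnot(inherits(lc, "limit_cycle"))
  if (is.character(pattern)) {
    if (pattern == "alternating") {
      if (is.null(lat)) stop("lat required for a named template")
      pattern <- alternating_phase_field(lat)
    } else stop("unknown template: ", pattern)
  }
  ph <- flatten_field(pattern)
  Xof <- orbit_interpolant(lc)
  st <- t(vapply(ph, function(phase) Xof(phase / lc$omega),
                 numeric(ncol(lc$orbit))))
  colnames(st) <- colnames(lc$orbit)
  st
}

#' Transient current perturbation protocol
#'
#' Extra applied current to a subset of cells over a time window, used to
#' probe stability and to switch the network between coexisting stable
#' cluster states.
#'
#' @param targets integer vector of 1-based flat site indices
#' @param delta_I extra applied current (uA/cm^2); either a scalar applied to
#'   every target or one value per target
#' @param t_on,t_off window (ms), `t_on < t_off`
#' @return an object of class `perturbation_protocol`
#' @export
perturbation_protocol <- function(targets, delta_I, t_on, t_off) {
  stopifnot(t_on < t_off, length(targets) >= 1,
            length(delta_I) %in% c(1L, length(targets)))
  structure(list(targets = as.integer(targets),
                 delta_I = rep_len(delta_I, length(targets)),
                 t_on = t_on, t_off = t_off),
            class = "perturbation_protocol")
}

# upward V = 0 crossings of one voltage trace, linear-interpolated times
detect_spikes <- function(times, V, threshold = 0) {
  i <- which(V[-length(V)] < threshold & V[-1] >= threshold)
  if (!length(i)) return(numeric(0))
  times[i] + (threshold - V[i]) / (V[i + 1] - V[i]) * (times[i + 1] - times[i])
}

#' Simulate the full biophysical torus network
#'
#' Integrates the 4N-dimensional Wang-Buzsaki network: each cell follows the
#' single-cell equations with synaptic current
#' `g_syn (V_i - V_syn) sum_j W_ij s_j`, where the connectivity `W` holds
#' dimensionless weights and `g_syn` comes from `params`. During an optional
#' protocol window the targeted cells receive `I_app + delta_I`. Spikes are
#' upward crossings of V = 0 mV with interpolated times.
#'
#' @param states N x 4 initial state matrix (see [init_from_pattern()])
#' @param conn a [build_connectivity()] matrix
#' @param params a [wb_params()]
#' @param duration total simulated time (ms)
#' @param protocol optional [perturbation_protocol()]
#' @param dt_out output sampling interval (ms) used for spike detection
#' @param rtol,atol integrator tolerances
#' @return object of class `spike_trains`: list with `spikes` (list of
#'   per-cell spike-time vectors), `final_states` (N x 4), `duration`,
#'   `threshold`
#' @export
simulate_biophysical <- function(states, conn, params = wb_params(),
                                 duration = 2000, protocol = NULL,
                                 dt_out = 0.5, rtol = 1e-6, atol = 1e-8) {
  states <- as.matrix(states)
  N <- nrow(states)
  stopifnot(ncol(states) == 4, nrow(conn) == N, ncol(conn) == N)
  W <- unclass(conn)
  iV <- 1:N; ih <- N + iV; in_ <- 2 * N + iV; is_ <- 3 * N + iV
  rhs <- function(t, y, p) {
    V <- y[iV]; h <- y[ih]; n <- y[in_]; s <- y[is_]
    r <- wb_rates(V)
    m_inf <- r$a_m / (r$a_m + r$b_m)
    drive <- as.vector(W %*% s)
    a_inh <- params$alpha0 / (1 + exp(-V / 5))
    dV <- (p$Iapp_vec -
             params$g_Na * m_inf^3 * h * (V - params$V_Na) -
             params$g_K * n^4 * (V - params$V_K) -
             params$g_L * (V - params$V_L) -
             params$g_syn * (V - params$V_syn) * drive) / params$C
    list(c(dV,
           params$gamma * (r$a_h * (1 - h) - r$b_h * h),
           params$gamma * (r$a_n * (1 - n) - r$b_n * n),
           -s / params$tau_inh + a_inh * (1 - s)))
  }
  base_I <- rep(params$I_app, N)
  segments <- if (is.null(protocol)) {
    list(list(t0 = 0, t1 = duration, I = base_I))
  } else {
    I_pert <- base_I
    I_pert[protocol$targets] <- I_pert[protocol$targets] + protocol$delta_I
    list(list(t0 = 0, t1 = protocol$t_on, I = base_I),
         list(t0 = protocol$t_on, t1 = protocol$t_off, I = I_pert),
         list(t0 = protocol$t_off, t1 = duration, I = base_I))
  }
  y <- c(states[, 1], states[, 2], states[, 3], states[, 4])
  spikes <- rep(list(numeric(0)), N)
  v_prev_t <- NULL; v_prev <- NULL
  for (seg in segments) {
    if (seg$t1 <= seg$t0) next
    tt <- seq(seg$t0, seg$t1, by = dt_out)
    if (tt[length(tt)] < seg$t1) tt <- c(tt, seg$t1)
    out <- deSolve::ode(y, tt, rhs, list(Iapp_vec = seg$I),
                        method = "lsoda", rtol = rtol, atol = atol)
    if (nrow(out) < length(tt))
      stop(sprintf("integration failure at t = %.1f ms", out[nrow(out), 1]))
    y <- out[nrow(out), -1]
    Vm <- out[, 1 + iV, drop = FALSE]
    for (cell in seq_len(N)) {
      tv <- out[, 1]; vv <- Vm[, cell]
      # include the boundary between segments so crossings there are caught
      if (!is.null(v_prev)) { tv <- c(v_prev_t, tv); vv <- c(v_prev[cell], vv) }
      sp <- detect_spikes(tv, vv)
      spikes[[cell]] <- c(spikes[[cell]], sp[sp > seg$t0 - dt_out])
    }
    v_prev_t <- out[nrow(out), 1]
    v_prev <- Vm[nrow(out), ]
  }
  spikes <- lapply(spikes, function(s) sort(unique(s)))
  final <- cbind(V = y[iV], h = y[ih], n = y[in_], s = y[is_])
  structure(list(spikes = spikes, final_states = final, duration = duration,
                 threshold = 0),
            class = "spike_trains")
}

#' @export
print.spike_trains <- function(x, ...) {
  ns <- lengths(x$spikes)
  cat(sprintf("spike trains: %d cells, %g ms, %d-%d spikes/cell\n",
              length(ns), x$duration, min(ns), max(ns)))
  invisible(x)
}

#' Simulate the reduced phase model on the torus
#'
#' Integrates `dtheta_ij/dt = Omega + eps sum_{(p,q)} w_pq
#' H(theta_{i+p,j+q} - theta_ij)` with H evaluated by periodic
#' interpolation.
#'
#' @param theta0 initial phases: m x n matrix or length-N row-major vector
#' @param w a [coupling_weights()]
#' @param H the interaction function ([interaction_fn()] or function)
#' @param lat a [torus_lattice()]
#' @param eps coupling strength epsilon (e.g. `g_syn`)
#' @param omega intrinsic frequency Omega (rad/ms)
#' @param duration simulated time (ms)
#' @param dt_out output interval (ms)
#' @return list with `times` and `theta` (rows = times, columns = sites,
#'   unwrapped phases)
#' @export
simulate_phase_model <- function(theta0, w, H, lat, eps, omega,
                                 duration = 2000, dt_out = 5) {
  hf <- as_hp(H)
  th0 <- if (is.matrix(theta0)) flatten_field(theta0) else as.numeric(theta0)
  stopifnot(length(th0) == lat$N)
  S <- w$offsets
  active <- which(w$w > 0)
  nbr <- lapply(active, function(r) {
    idx <- integer(lat$N)
    for (j in 0:(lat$m - 1)) for (i in 0:(lat$n - 1))
      idx[site_index(i, j, lat)] <- site_index(i + S[r, 1], j + S[r, 2], lat)
    idx
  })
  ww <- w$w[active]
  rhs <- function(t, th, p) {
    dth <- rep(omega, lat$N)
    for (a in seq_along(active))
      dth <- dth + eps * ww[a] * hf(th[nbr[[a]]] - th)
    list(dth)
  }
  tt <- seq(0, duration, by = dt_out)
  out <- deSolve::ode(th0, tt, rhs, NULL, method = "lsoda",
                      rtol = 1e-8, atol = 1e-10)
  list(times = out[, 1], theta = out[, -1, drop = FALSE])
}

#' Empirical phase field from spike trains
#'
#' Reads out per-cell phases from the steady firing at the end of a
#' simulation. The network period is the mean inter-spike interval of the
#' reference cell (site 1) over the last `k` periods; each cell's phase is
#' the circular mean of `-2 pi * offset / T` over those periods, where
#' `offset` is the cell's spike time minus the preceding reference spike.
#' (The minus sign: a cell whose oscillator phase leads the reference fires
#' earlier, i.e. at negative offset.)
#'
#' @param spikes a `spike_trains` object
#' @param lat a [torus_lattice()]
#' @param window time window `c(t0, t1)` to use (default: last 40% of run)
#' @param k number of reference periods to average (default 5)
#' @return a `phase_field` m x n matrix of phases relative to site 1
#' @export
empirical_phases <- function(spikes, lat, window = NULL, k = 5) {
  stopifnot(inherits(spikes, "spike_trains"))
  if (is.null(window)) window <- c(0.6, 1) * spikes$duration
  clip <- lapply(spikes$spikes, function(s) s[s >= window[1] & s <= window[2]])
  if (any(lengths(clip) < 3)) stop("silent cell: fewer than 3 spikes in window")
  ref <- clip[[1]]
  ref <- utils::tail(ref, k + 1)
  T_net <- mean(diff(ref))
  refs <- ref[-length(ref)]
  ph <- vapply(seq_len(lat$N), function(cell) {
    zs <- vapply(refs, function(r0) {
      cand <- clip[[cell]]
      cand <- cand[cand >= r0 & cand < r0 + T_net]
      if (!length(cand)) return(NA_complex_)
      exp(-2i * pi * (cand[1] - r0) / T_net)
    }, complex(1))
    zs <- zs[!is.na(zs)]
    if (!length(zs)) stop("silent cell: no spike within a reference period")
    Arg(mean(zs)) %% (2 * pi)
  }, 0)
  structure(matrix(ph, lat$m, lat$n, byrow = TRUE),
            class = c("phase_field", "matrix"))
}

#' Compare two phase fields up to a global shift
#'
#' TRUE iff a single global phase shift aligns the two fields with every
#' per-site circular difference below `tol`. The shift is estimated as the
#' circular mean of the differences.
#'
#' @param observed,target `phase_field` matrices (same dimensions)
#' @param tol per-site circular tolerance (rad); the default corresponds to
#'   2 ms of a 50 ms period
#' @return logical
#' @export
matches_pattern <- function(observed, target, tol = 2 * pi * 2 / 50) {
  a <- flatten_field(observed)
  b <- flatten_field(target)
  stopifnot(length(a) == length(b))
  shift <- Arg(mean(exp(1i * (a - b))))
  all(circ_dist(a, b + shift) < tol)
}

# run fn with a private RNG seed, restoring the caller's RNG state
with_seed <- function(seed, fn) {
  has <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (has) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  fn()
}

#' Empirical stability of a firing pattern
#'
#' Perturb-and-relax protocol: the network is initialized exactly on the
#' candidate pattern, a small transient current is applied to a fixed
#' pseudo-random half of the cells, the network then evolves freely, and the
#' final empirical phase field is compared to the initial pattern up to a
#' global phase shift. Stable patterns reabsorb the perturbation; unstable
#' ones drift to a different attractor.
#'
#' The probe must be gentle: with strong coupling the basins of attraction of
#' coexisting cluster states shrink, and a large pulse measures basin
#' geometry (the switching experiments) rather than local stability. The
#' default amplitude, 1/200 of the driving current for two firing periods,
#' displaces phases by a few hundredths of a radian -- large enough that a
#' linearly unstable mode grows to a detectable level within the relaxation
#' window, small enough to stay inside the narrow basins that accompany
#' strong diagonal coupling.
#'
#' A cell that falls silent during relaxation (suppressed by reorganized
#' inhibition) means the pattern was not maintained, so the function returns
#' FALSE in that case.
#'
#' With many coexisting attractors the return-or-escape outcome of a single
#' pulse depends on the direction of the perturbation (which cells were hit):
#' one probe samples the basin's angular measure once. For threshold
#' measurements, set `n_probes > 1` to repeat the protocol with independent
#' pseudo-random subsets (seeds `seed, seed + 1, ...`) and take the majority
#' verdict, which estimates whether most small perturbation directions are
#' reabsorbed.
#'
#' @param pattern phase-field matrix or `"alternating"`
#' @param lat a [torus_lattice()]
#' @param w a [coupling_weights()]
#' @param lc a [limit_cycle()] for the cell model in `params`
#' @param params a [wb_params()]
#' @param delta_I perturbation amplitude (uA/cm^2)
#' @param t_settle time before the perturbation (ms)
#' @param t_pulse perturbation duration (ms)
#' @param t_relax free evolution after the pulse (ms)
#' @param seed seed for the pseudo-random choice of perturbed cells
#' @param tol pattern-match tolerance (rad); default 2 ms of the cell period
#' @param n_probes number of independent probe subsets; the majority verdict
#'   is returned (default 1: a single probe)
#' @return logical: did the network return to the initial pattern?
#' @export
is_empirically_stable <- function(pattern, lat, w, lc, params = lc$params,
                                  delta_I = 0.002, t_settle = 200,
                                  t_pulse = 100, t_relax = 2700,
                                  seed = 1234L, tol = NULL, n_probes = 1L) {
  if (is.character(pattern)) {
    if (pattern == "alternating") pattern <- alternating_phase_field(lat)
    else stop("unknown template: ", pattern)
  }
  if (is.null(tol)) tol <- 2 * pi * 2 / lc$T
  conn <- build_connectivity(lat, w)
  st <- init_from_pattern(pattern, lc, lat)
  duration <- t_settle + t_pulse + t_relax
  one_probe <- function(probe_seed) {
    targets <- with_seed(probe_seed,
                         function() sort(sample(lat$N, lat$N %/% 2)))
    prot <- perturbation_protocol(targets, delta_I,
                                  t_on = t_settle,
                                  t_off = t_settle + t_pulse)
    run <- simulate_biophysical(st, conn, params, duration, protocol = prot)
    obs <- tryCatch(empirical_phases(run, lat), error = function(e) NULL)
    if (is.null(obs)) return(FALSE)
    matches_pattern(obs, pattern, tol = tol)
  }
  votes <- vapply(seq_len(n_probes) - 1L,
                  function(k) one_probe(seed + k), TRUE)
  sum(votes) > n_probes / 2
}
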