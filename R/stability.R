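#' Coupling stencil
#'
#' The 12 offsets a site is coupled to: 4 nearest neighbors (horizontal,
#' vertical), 4 diagonal neighbors, and 4 second-nearest neighbors
#' (horizontal, vertical), all with torus wraparound.
#'
#' @return 12 x 2 integer matrix of (p, q) offsets
#' @export
coupling_stencil <- function() {
  matrix(c(1, 0, -1, 0, 0, 1, 0, -1,
           -1, 1, 1, 1, 1, -1, -1, -1,
           2, 0, -2, 0, 0, 2, 0, -2),
         ncol = 2, byrow = TRUE,
         dimnames = list(NULL, c("p", "q")))
}

#' Coupling weights over the stencil
#'
#' Either the symmetric shorthand (`h1` on the four nearest horizontal and
#' vertical... specifically `w_{+-1,0} = h1`, `w_{0,+-1} = v1`,
#' `w_{+-1,+-1} = d`, `w_{+-2,0} = h2`, `w_{0,+-2} = v2`) or a general
#' offset-to-weight map restricted to the stencil. Weights are dimensionless
#' multipliers of the coupling parameter epsilon = `g_syn`.
#'
#' @param h1,v1,d,h2,v2 symmetric shorthand weights (all >= 0)
#' @param map optional data.frame with columns `p`, `q`, `w` giving a general
#'   (possibly asymmetric) weight per offset; overrides the shorthand
#' @return an object of class `coupling_weights`: the stencil with a weight
#'   per offset
#' @export
coupling_weights <- function(h1 = 0, v1 = 0, d = 0, h2 = 0, v2 = 0,
                             map = NULL) {
  S <- coupling_stencil()
  if (is.null(map)) {
    stopifnot(h1 >= 0, v1 >= 0, d >= 0, h2 >= 0, v2 >= 0)
    w <- c(h1, h1, v1, v1, d, d, d, d, h2, h2, v2, v2)
    symmetric <- TRUE
  } else {
    stopifnot(all(c("p", "q", "w") %in% names(map)), all(map$w >= 0))
    key <- paste(S[, 1], S[, 2])
    mkey <- paste(map$p, map$q)
    if (!all(mkey %in% key)) stop("weight offset outside the stencil")
    if (anyDuplicated(mkey)) stop("duplicated offsets in weight map")
    w <- numeric(nrow(S))
    w[match(mkey, key)] <- map$w
    symmetric <- all(w == w[c(2, 1, 4, 3, 7, 8, 5, 6, 10, 9, 12, 11)])
  }
  structure(list(offsets = S, w = w, symmetric = symmetric),
            class = "coupling_weights")
}

#' @export
print.coupling_weights <- function(x, ...) {
  if (x$symmetric) {
    cat(sprintf("coupling weights (symmetric): h1 = %g, v1 = %g, d = %g, h2 = %g, v2 = %g\n",
                x$w[1], x$w[3], x$w[5], x$w[9], x$w[11]))
  } else {
    cat("coupling weights (general):\n")
    print(data.frame(x$offsets, w = x$w))
  }
  invisible(x)
}

# Resolve a derivative evaluator from an interaction_fn or a function
as_hp <- function(Hp) {
  if (inherits(Hp, "interaction_fn")) return(function(psi) if_eval(Hp, psi))
  if (is.function(Hp)) return(Hp)
  stop("Hp must be a function or an interaction_fn")
}

psi_of <- function(sol) {
  if (inherits(sol, "cluster_solution")) c(sol$psi_h, sol$psi_v)
  else if (is.numeric(sol) && length(sol) == 2) as.numeric(sol)
  else stop("sol must be a cluster_solution or c(psi_h, psi_v)")
}

#' Closed-form eigenvalue real parts of a cluster solution
#'
#' Real parts of the eigenvalues of the linearization `J = -c I + What`
#' around a constant-step cluster solution, from the block-circulant closed
#' form indexed by lattice wavenumbers `(j, k)`:
#' `Re lambda_jk = -sum_{(p,q) in S} w_pq H'(p psi_h + q psi_v)
#'   (1 - cos(2 pi (j p / n + k q / m)))`.
#' For symmetric weights the paired offsets combine via
#' `H'(x) + H'(-x) = 2 H'_odd(x)`, recovering the symmetric-case formula
#' exactly. The coupling parameter epsilon > 0 scales all eigenvalues and is
#' taken as 1.
#'
#' @param sol a [cluster_solution()] or numeric `c(psi_h, psi_v)`
#' @param w a [coupling_weights()]
#' @param Hp evaluator of H': a function of phase or an [interaction_fn()]
#'   holding the tabulated derivative
#' @param lat a [torus_lattice()]
#' @return object of class `eigen_grid`: list with `re` (n x m matrix,
#'   `re[j+1, k+1]` for wavenumbers j, k), effective rate `c`, and metadata
#' @export
eigen_real_parts <- function(sol, w, Hp, lat) {
  stopifnot(inherits(w, "coupling_weights"), inherits(lat, "torus_lattice"))
  hp <- as_hp(Hp)
  psi <- psi_of(sol)
  S <- w$offsets
  hvals <- vapply(seq_len(nrow(S)),
                  function(r) hp((S[r, 1] * psi[1] + S[r, 2] * psi[2]) %% (2 * pi)),
                  0)
  what <- w$w * hvals
  # an offset that wraps to the cell itself (possible when n or m <= 2) is
  # self-coupling and cancels out of the linearization entirely
  what[S[, 1] %% lat$n == 0 & S[, 2] %% lat$m == 0] <- 0
  cc <- sum(what)
  jj <- 0:(lat$n - 1)
  kk <- 0:(lat$m - 1)
  re <- matrix(0, lat$n, lat$m)
  for (r in seq_len(nrow(S))) {
    ang <- outer(jj * S[r, 1] / lat$n, kk * S[r, 2] / lat$m, `+`)
    re <- re - what[r] * (1 - cos(2 * pi * ang))
  }
  structure(list(re = re, c = cc, psi_h = psi[1], psi_v = psi[2],
                 m = lat$m, n = lat$n, weights = w),
            class = "eigen_grid")
}

#' @export
print.eigen_grid <- function(x, ...) {
  nz <- x$re[-1]
  cat(sprintf("eigen grid %dx%d: Re lambda_00 = %.3g, nonzero modes in [%.4g, %.4g], c = %.4g\n",
              x$n, x$m, x$re[1, 1], min(nz), max(nz), x$c))
  invisible(x)
}

#' Dense Jacobian of the phase-model linearization
#'
#' Assembles the full N x N matrix `J = -c I + What` entry by entry from the
#' linearization of the phase model around a cluster solution (row-major site
#' order): entry (site, site at offset (p,q)) accumulates
#' `w_pq H'(p psi_h + q psi_v)` and the diagonal is `-c`. Offsets that
#' coincide on small lattices (e.g. +2 and -2 when n = 4) are summed into the
#' same entry, exactly as the mod arithmetic implies. The full spectrum of
#' this matrix is the independent check of the closed form.
#'
#' @inheritParams eigen_real_parts
#' @return N x N numeric matrix
#' @export
jacobian_oracle <- function(sol, w, Hp, lat) {
  hp <- as_hp(Hp)
  psi <- psi_of(sol)
  S <- w$offsets
  N <- lat$N
  J <- matrix(0, N, N)
  hvals <- vapply(seq_len(nrow(S)),
                  function(r) hp((S[r, 1] * psi[1] + S[r, 2] * psi[2]) %% (2 * pi)),
                  0)
  what <- w$w * hvals
  what[S[, 1] %% lat$n == 0 & S[, 2] %% lat$m == 0] <- 0  # self-coupling
  for (j in 0:(lat$m - 1)) {
    for (i in 0:(lat$n - 1)) {
      row <- site_index(i, j, lat)
      for (r in seq_len(nrow(S))) {
        col <- site_index(i + S[r, 1], j + S[r, 2], lat)
        J[row, col] <- J[row, col] + what[r]
      }
      J[row, row] <- J[row, row] - sum(what)
    }
  }
  J
}

#' Classify an eigenvalue grid
#'
#' The uniform phase-shift mode `(j, k) = (0, 0)` is always zero and is
#' excluded. The solution is stable if every other mode has
#' `Re lambda < -tol`, unstable if any has `Re lambda > tol`, and marginal
#' if a nonzero mode lies within the tolerance band.
#'
#' @param grid an [eigen_real_parts()] result
#' @param tol zero-mode tolerance; default scales with the effective rate `c`
#' @return object of class `stability_verdict` with elements `verdict`
#'   (`"stable"`, `"unstable"` or `"marginal"`), `max_re` (largest nonzero
#'   mode) and `tol`
#' @export
classify <- function(grid, tol = NULL) {
  stopifnot(inherits(grid, "eigen_grid"))
  if (is.null(tol)) tol <- 1e-9 * max(1, abs(grid$c))
  nz <- grid$re[-1]   # drop (0,0); column-major first element is [1,1]
  mx <- max(nz)
  verdict <- if (mx > tol) "unstable"
             else if (all(nz < -tol)) "stable"
             else "marginal"
  structure(list(verdict = verdict, max_re = mx, tol = tol),
            class = "stability_verdict")
}

#' @export
print.stability_verdict <- function(x, ...) {
  cat(sprintf("%s (max nonzero-mode Re lambda = %.4g)\n", x$verdict, x$max_re))
  invisible(x)
}

#' Stability table over all cluster solutions of a lattice
#'
#' Enumerates every constant-step cluster solution of the lattice, evaluates
#' the closed-form eigenvalue real parts, and classifies each.
#'
#' @param lat a [torus_lattice()]
#' @param w a [coupling_weights()]
#' @param Hp evaluator of H' (function or [interaction_fn()])
#' @param tol zero-mode tolerance passed to [classify()]
#' @return data.frame keyed by `(psi_h, psi_v)` with cluster structure,
#'   verdict and the largest nonzero-mode eigenvalue real part
#' @export
stability_table <- function(lat, w, Hp, tol = NULL) {
  sols <- enumerate_solutions(lat$m, lat$n)
  hp <- as_hp(Hp)
  res <- lapply(seq_len(nrow(sols)), function(r) {
    g <- eigen_real_parts(c(sols$psi_h[r], sols$psi_v[r]), w, hp, lat)
    v <- classify(g, tol)
    data.frame(verdict = v$verdict, max_re = v$max_re)
  })
  cbind(sols, do.call(rbind, res))
}

#' Critical diagonal-to-nearest coupling ratio
#'
#' The 2-cluster diagonal-stripe solution (`psi_h = psi_v = pi`) loses
#' stability when the diagonal weight exceeds
#' `-H'_odd(pi) / (2 H'_odd(0)) * min(h1, v1)`; this returns that
#' scale-invariant ratio. Requires the sign structure
#' `H'_odd(0) < 0 < H'_odd(pi)` (otherwise no finite threshold exists).
#'
#' @param Hp_odd evaluator of the odd-part derivative `H'_odd` (function or
#'   [interaction_fn()])
#' @return critical ratio `d / min(h1, v1)` (scalar)
#' @export
diagonal_destabilization_ratio <- function(Hp_odd) {
  hp <- as_hp(Hp_odd)
  h0 <- hp(0)
  hpi <- hp(pi)
  if (!(h0 < 0 && hpi > 0))
    stop("need H'_odd(0) < 0 < H'_odd(pi) for a finite threshold")
  -hpi / (2 * h0)
}

#' Root-found critical diagonal coupling
#'
#' Locates, by bisection on the full eigenvalue grid, the diagonal weight `d`
#' at which the largest nonzero-mode eigenvalue real part of the
#' `(pi, pi)` diagonal-stripe solution crosses zero, with `h1 = v1` fixed.
#' Cross-validates [diagonal_destabilization_ratio()].
#'
#' @param Hp evaluator of H' (the full derivative, not the odd part)
#' @param lat a [torus_lattice()]
#' @param h1,v1 nearest-neighbor weights
#' @param d_max upper end of the search bracket
#' @return critical `d` (scalar)
#' @export
critical_diagonal_coupling <- function(Hp, lat = torus_lattice(6, 6),
                                       h1 = 1, v1 = 1, d_max = 20) {
  hp <- as_hp(Hp)
  f <- function(d) {
    g <- eigen_real_parts(c(pi, pi), coupling_weights(h1 = h1, v1 = v1, d = d),
                          hp, lat)
    max(g$re[-1])
  }
  if (f(0) >= 0) stop("(pi, pi) solution is not stable at d = 0")
  if (f(d_max) <= 0) stop("no destabilization up to d_max")
  stats::uniroot(f, c(0, d_max), tol = 1e-10)$root
}

#' Necessary condition for horizontal-stripe stability
#'
#' For a p-cluster horizontal stripe (`psi_h = 0`, vertical step `psi_v`),
#' the modes with k = 0 have real part proportional to
#' `-(2 d H'_odd(psi_v) + h1 H'_odd(0))`; the stripe can only be stable if
#' `2 d H'_odd(psi_v) + h1 H'_odd(0) > 0`. This is necessary, not
#' sufficient: use [classify()] on the full grid for the verdict.
#'
#' @param Hp_odd evaluator of `H'_odd`
#' @param psi_v vertical phase step (rad)
#' @param h1 nearest-neighbor horizontal weight
#' @param d diagonal weight
#' @return logical
#' @export
horizontal_stripe_condition <- function(Hp_odd, psi_v, h1, d) {
  hp <- as_hp(Hp_odd)
  2 * d * hp(psi_v) + h1 * hp(0) > 0
}

#' Frequency correction of a cluster solution
#'
#' The O(epsilon) correction to the common drift rate of a phase-locked
#' cluster solution: `omega = sum_{(p,q) in S} w_pq H(p psi_h + q psi_v)`.
#'
#' @param sol a [cluster_solution()] or `c(psi_h, psi_v)`
#' @param w a [coupling_weights()]
#' @param H the interaction function (function or [interaction_fn()])
#' @return scalar `omega`
#' @export
frequency_correction <- function(sol, w, H) {
  hf <- as_hp(H)
  psi <- psi_of(sol)
  S <- w$offsets
  sum(w$w * vapply(seq_len(nrow(S)),
                   function(r) hf((S[r, 1] * psi[1] + S[r, 2] * psi[2]) %% (2 * pi)),
                   0))
}
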