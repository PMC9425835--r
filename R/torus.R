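#' Torus lattice
#'
#' An m x n lattice with periodic boundary conditions. Sites are indexed
#' `(i, j)` with `i` in `0..n-1` horizontal (columns) and `j` in `0..m-1`
#' vertical (rows); all offset arithmetic is mod n horizontally and mod m
#' vertically. The flat site order is row-major:
#' `(0,0), (1,0), ..., (n-1,0), (0,1), ...`, i.e. flat index `i + n*j + 1`.
#'
#' @param m number of rows (vertical extent)
#' @param n number of columns (horizontal extent)
#' @return an object of class `torus_lattice`
#' @export
torus_lattice <- function(m, n) {
  stopifnot(m >= 1, n >= 1, m == round(m), n == round(n))
  structure(list(m = as.integer(m), n = as.integer(n),
                 N = as.integer(m * n)),
            class = "torus_lattice")
}

#' @export
print.torus_lattice <- function(x, ...) {
  cat(sprintf("torus lattice: %d rows x %d columns (%d sites)\n",
              x$m, x$n, x$N))
  invisible(x)
}

# flat (row-major) index of site (i, j), both 0-based, with wraparound
site_index <- function(i, j, lat) {
  (i %% lat$n) + lat$n * (j %% lat$m) + 1L
}

divisors <- function(x) (1:x)[x %% (1:x) == 0]

# integers l in [0, p) coprime to p, with l = 0 only for p = 1
coprime_residues <- function(p) {
  if (p == 1) return(0L)
  ls <- seq_len(p - 1)
  ls[vapply(ls, function(l) gcd2(l, p) == 1L, TRUE)]
}

gcd2 <- function(a, b) if (b == 0) a else gcd2(b, a %% b)
lcm2 <- function(a, b) a * b / gcd2(a, b)

#' Cluster solution on a torus
#'
#' A phase-locked solution with constant phase steps
#' `psi_h = 2 pi l_h / p_h` between horizontal neighbors and
#' `psi_v = 2 pi l_v / p_v` between vertical neighbors. Admissibility on an
#' m x n torus requires `p_h | n` and `p_v | m`; the network splits into
#' `p = lcm(p_h, p_v)` equal clusters.
#'
#' @param p_h,p_v number of clusters along the horizontal / vertical direction
#' @param l_h,l_v winding integers, coprime to `p_h` / `p_v` (0 only with
#'   `p = 1`)
#' @return an object of class `cluster_solution`
#' @export
cluster_solution <- function(p_h = 1, l_h = 0, p_v = 1, l_v = 0) {
  chk <- function(p, l) {
    stopifnot(p >= 1, l >= 0, l < max(p, 1))
    if (p == 1) stopifnot(l == 0) else stopifnot(gcd2(l, p) == 1)
  }
  chk(p_h, l_h); chk(p_v, l_v)
  structure(list(p_h = p_h, l_h = l_h, p_v = p_v, l_v = l_v,
                 psi_h = (2 * pi * l_h / p_h) %% (2 * pi),
                 psi_v = (2 * pi * l_v / p_v) %% (2 * pi),
                 p = lcm2(p_h, p_v)),
            class = "cluster_solution")
}

#' @export
print.cluster_solution <- function(x, ...) {
  cat(sprintf("(%d, %d) %d-cluster solution: psi_h = %.4f, psi_v = %.4f rad\n",
              x$p_h, x$p_v, x$p, x$psi_h, x$psi_v))
  invisible(x)
}

#' Enumerate all cluster solutions of an m x n torus
#'
#' One solution per admissible `(p_h, l_h, p_v, l_v)`: `p_h` runs over
#' divisors of `n`, `p_v` over divisors of `m`, and the winding numbers over
#' residues coprime to the cluster number. Distinct `(psi_h, psi_v)` pairs
#' are all counted (including the mirrored diagonal variants); the
#' synchronous solution `(1, 1)` is included. The per-direction count is
#' `sum over p | n of EulerPhi(p)`.
#'
#' @param m,n lattice dimensions (rows, columns)
#' @return a data.frame with columns p_h, l_h, p_v, l_v, psi_h, psi_v, p and
#'   a list-column free representation; one row per solution
#' @export
enumerate_solutions <- function(m, n) {
  lat <- torus_lattice(m, n)
  one_dir <- function(size) {
    do.call(rbind, lapply(divisors(size), function(p)
      data.frame(p = p, l = coprime_residues(p))))
  }
  hs <- one_dir(lat$n)
  vs <- one_dir(lat$m)
  grid <- expand.grid(h = seq_len(nrow(hs)), v = seq_len(nrow(vs)))
  out <- data.frame(p_h = hs$p[grid$h], l_h = hs$l[grid$h],
                    p_v = vs$p[grid$v], l_v = vs$l[grid$v])
  out$psi_h <- (2 * pi * out$l_h / out$p_h) %% (2 * pi)
  out$psi_v <- (2 * pi * out$l_v / out$p_v) %% (2 * pi)
  out$p <- mapply(lcm2, out$p_h, out$p_v)
  stopifnot(!anyDuplicated(out[, c("psi_h", "psi_v")]))
  out[order(out$p, out$p_h, out$p_v, out$l_h, out$l_v), , drop = FALSE]
}

#' Phase field of a cluster solution
#'
#' The constant-step phase offsets `phi_ij = (i psi_h + j psi_v) mod 2pi`
#' over the lattice.
#'
#' @param sol a [cluster_solution()] (or anything with `psi_h`, `psi_v`)
#' @param lat a [torus_lattice()]
#' @return an m x n matrix of phases (rows = j = vertical index, columns =
#'   i = horizontal index), class `phase_field`
#' @export
phase_field <- function(sol, lat) {
  if (inherits(sol, "cluster_solution")) {
    if (lat$n %% sol$p_h != 0 || lat$m %% sol$p_v != 0)
      stop("solution is not admissible on this lattice (divisibility)")
  }
  i <- 0:(lat$n - 1)
  j <- 0:(lat$m - 1)
  f <- outer(j, i, function(jj, ii) (ii * sol$psi_h + jj * sol$psi_v) %% (2 * pi))
  structure(f, class = c("phase_field", "matrix"))
}

# flatten an m x n phase field to the row-major site vector
flatten_field <- function(field) as.vector(t(unclass(field)))

# circular distance between phases
circ_dist <- function(a, b) {
  d <- (a - b) %% (2 * pi)
  pmin(d, 2 * pi - d)
}

#' Partition lattice sites into clusters by phase
#'
#' Groups sites whose phases agree within `tol` (circular distance), and
#' returns the groups sorted by phase. Site numbers are the 1-based row-major
#' flat indices.
#'
#' @param field a [phase_field()] matrix
#' @param tol phase tolerance (rad)
#' @return list of integer vectors (site indices), one per cluster, with the
#'   cluster phase attached as attribute `phase`
#' @export
cluster_partition <- function(field, tol = 1e-9) {
  ph <- flatten_field(field)
  groups <- list()
  centers <- numeric(0)
  for (site in order(ph)) {
    placed <- FALSE
    for (g in seq_along(groups)) {
      if (circ_dist(ph[site], centers[g]) <= tol) {
        groups[[g]] <- c(groups[[g]], site)
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      groups[[length(groups) + 1]] <- site
      centers <- c(centers, ph[site])
    }
  }
  o <- order(centers)
  out <- lapply(o, function(g) sort(groups[[g]]))
  for (g in seq_along(out)) attr(out[[g]], "phase") <- centers[o[g]]
  out
}
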