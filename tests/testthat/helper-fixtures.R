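# Shared fixtures. The biophysically derived interaction function is needed
# by several files; it is computed once per test run and cached.

.cache <- new.env(parent = emptyenv())

table1_lc <- function(n_grid = 1024) {
  key <- paste0("lc", n_grid)
  if (is.null(.cache[[key]]))
    .cache[[key]] <- compute_adjoint(find_limit_cycle(wb_params(),
                                                      n_grid = n_grid))
  .cache[[key]]
}

table1_H <- function(n_grid = 1024) {
  key <- paste0("H", n_grid)
  if (is.null(.cache[[key]]))
    .cache[[key]] <- interaction_function(table1_lc(n_grid))
  .cache[[key]]
}

table1_Hp <- function() if_derivative(table1_H())
table1_Hop <- function() if_derivative(odd_part(table1_H()))

flat <- function(field) as.vector(t(unclass(field)))

# random admissible cluster solution for an m x n torus
rand_solution <- function(m, n) {
  pick <- function(size) {
    p <- sample((1:size)[size %% (1:size) == 0], 1)
    ls <- if (p == 1) 0L else {
      cand <- seq_len(p - 1)
      cand[vapply(cand, function(l) torusphase:::gcd2(l, p) == 1L, TRUE)]
    }
    c(p, if (length(ls) == 1) ls else sample(ls, 1))
  }
  h <- pick(n); v <- pick(m)
  cluster_solution(h[1], h[2], v[1], v[2])
}

# random smooth 2pi-periodic function (low-order trigonometric polynomial)
rand_trig <- function() {
  a <- stats::rnorm(3, sd = 1)
  b <- stats::rnorm(3, sd = 1)
  c0 <- stats::rnorm(1)
  function(psi) {
    out <- rep(c0, length(psi))
    for (k in 1:3) out <- out + a[k] * cos(k * psi) + b[k] * sin(k * psi)
    out
  }
}
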