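test_that("connectivity rows realize the stencil neighborhoods", {
  lat <- torus_lattice(6, 6)
  # 8 nearest neighbors
  W8 <- build_connectivity(lat, coupling_weights(h1 = 1, v1 = 1, d = 1))
  expect_true(all(rowSums(W8 > 0) == 8))
  expect_true(all(rowSums(W8) == 8))
  expect_true(all(diag(W8) == 0))
  expect_true(isSymmetric(unclass(W8)))
  # full stencil: 12 neighbors
  W12 <- build_connectivity(lat, coupling_weights(1, 1, 1, 1, 1))
  expect_true(all(rowSums(W12 > 0) == 12))
  expect_true(all(rowSums(W12) == 12))
  # neighbors sit at the stencil offsets
  S <- coupling_stencil()
  nb <- which(W12[1, ] > 0)  # site (0, 0)
  exp_nb <- sort(unique(vapply(seq_len(nrow(S)), function(r)
    torusphase:::site_index(S[r, 1], S[r, 2], lat), 0)))
  expect_equal(sort(nb), exp_nb)
})

test_that("coinciding offsets on small lattices are summed with a warning", {
  lat4 <- torus_lattice(4, 4)
  # on a 4-torus the +2 and -2 offsets reach the same site in each direction
  expect_warning(
    W <- build_connectivity(lat4, coupling_weights(1, 1, 1, 1, 1)),
    "coincide")
  expect_true(all(rowSums(W > 0) == 10))
  expect_true(all(rowSums(W) == 12))
  expect_equal(max(W), 2)  # the doubled second-neighbor entries
})

test_that("pattern initialization places cells on the orbit at their phases", {
  lc <- table1_lc(256)
  lat <- torus_lattice(6, 6)
  sync <- init_from_pattern(phase_field(cluster_solution(), lat), lc, lat)
  expect_equal(nrow(sync), 36)
  expect_true(all(apply(sync, 2, function(x) max(x) - min(x)) == 0))

  diag2 <- init_from_pattern(phase_field(cluster_solution(2, 1, 2, 1), lat),
                             lc, lat)
  states <- unique(round(diag2, 9))
  expect_equal(nrow(states), 2)
  # the two states are half a period apart on the orbit
  expect_equal(unname(states[2, ]),
               unname(lc$orbit[lc$n_grid / 2 + 1, ]), tolerance = 1e-5)

  expect_error(init_from_pattern("no-such-template", lc, lat), "unknown")
})

test_that("the alternating 4-cluster template matches the row-major cell lists", {
  lat4 <- torus_lattice(4, 4)
  f <- alternating_phase_field(lat4)
  part <- cluster_partition(f)
  by_phase <- lapply(part, as.integer)
  names(by_phase) <- vapply(part, function(g)
    sprintf("%.2f", attr(g, "phase") / pi), "")
  expect_equal(by_phase[["0.00"]], c(1L, 3L, 9L, 11L))
  expect_equal(by_phase[["0.50"]], c(2L, 4L, 10L, 12L))
  expect_equal(by_phase[["1.00"]], c(6L, 8L, 14L, 16L))
  expect_equal(by_phase[["1.50"]], c(5L, 7L, 13L, 15L))
})

test_that("decoupled cells fire at the isolated period; synchrony is invariant", {
  lc <- table1_lc(256)
  lat <- torus_lattice(3, 3)
  # zero coupling: every cell keeps the single-cell period
  p0 <- wb_params(g_syn = 0)
  conn <- build_connectivity(lat, coupling_weights(h1 = 1, v1 = 1))
  st <- init_from_pattern(phase_field(cluster_solution(), lat), lc, lat)
  run <- simulate_biophysical(st, conn, p0, duration = 300)
  for (cell in 1:9)
    expect_equal(mean(diff(run$spikes[[cell]])), lc$T, tolerance = 1e-3)
  # exact synchronous start with homogeneous coupling stays synchronous
  run2 <- simulate_biophysical(st, conn, lc$params, duration = 300)
  ref <- run2$spikes[[1]]
  for (cell in 2:9)
    expect_equal(run2$spikes[[cell]], ref, tolerance = 1e-6)
})

test_that("perturbation protocol windows are validated and applied", {
  expect_error(perturbation_protocol(1:3, 0.1, t_on = 100, t_off = 50),
               "t_on")
  lc <- table1_lc(256)
  lat <- torus_lattice(2, 2)
  # +1 and -1 offsets coincide on a 2-torus; the summed weights are intended
  conn <- suppressWarnings(
    build_connectivity(lat, coupling_weights(h1 = 1, v1 = 1)))
  st <- init_from_pattern(phase_field(cluster_solution(), lat), lc, lat)
  # a strong pulse to one cell desynchronizes it from the others
  prot <- perturbation_protocol(1, delta_I = 0.3, t_on = 50, t_off = 150)
  run <- simulate_biophysical(st, conn, lc$params, duration = 300,
                              protocol = prot)
  late1 <- run$spikes[[1]][run$spikes[[1]] > 200]
  late2 <- run$spikes[[2]][run$spikes[[2]] > 200]
  expect_gt(min(abs(outer(late1, late2, `-`))), 0.5)
})

test_that("empirical phases recover known spike-train structure", {
  lat <- torus_lattice(2, 2)
  T_net <- 50
  mk <- function(offsets, duration = 1000) {
    structure(list(
      spikes = lapply(offsets, function(o) seq(o %% T_net, duration, by = T_net)),
      final_states = NULL, duration = duration, threshold = 0),
      class = "spike_trains")
  }
  # synchronous: all phases 0
  ph <- empirical_phases(mk(c(0, 0, 0, 0)), lat)
  expect_lt(max(abs(ph)), 1e-9)
  # cell firing a quarter period later than the reference leads by -pi/2,
  # i.e. its oscillator phase is 3 pi / 2
  ph2 <- empirical_phases(mk(c(0, T_net / 4, T_net / 2, 0)), lat)
  expect_equal(ph2[1, 2], 3 * pi / 2, tolerance = 1e-9)
  expect_equal(ph2[2, 1], pi, tolerance = 1e-9)
  # silent cell is an error
  bad <- mk(c(0, 0, 0, 0))
  bad$spikes[[3]] <- numeric(0)
  expect_error(empirical_phases(bad, lat), "silent")
})

test_that("pattern matching is invariant to a global phase shift only", {
  lat <- torus_lattice(6, 6)
  f <- phase_field(cluster_solution(2, 1, 3, 1), lat)
  expect_true(matches_pattern(f, f))
  shifted <- structure((unclass(f) + 1.3) %% (2 * pi),
                       class = c("phase_field", "matrix"))
  expect_true(matches_pattern(shifted, f))
  hor <- phase_field(cluster_solution(1, 0, 2, 1), lat)
  ver <- phase_field(cluster_solution(2, 1, 1, 0), lat)
  expect_false(matches_pattern(hor, ver))
})

test_that("phase model holds cluster solutions with drift Omega + eps*omega", {
  fx <- analytic_fixtures(512)
  H <- fx$two_harmonic
  lat <- torus_lattice(6, 6)
  w <- coupling_weights(h1 = 1, v1 = 1, d = 0.5)
  sol <- cluster_solution(2, 1, 2, 1)
  th0 <- phase_field(sol, lat)
  eps <- 0.05; omega0 <- 0.12
  run <- simulate_phase_model(th0, w, H, lat, eps = eps, omega = omega0,
                              duration = 500)
  th_end <- unname(run$theta[nrow(run$theta), ])
  # phase differences unchanged
  d0 <- flat(th0) - flat(th0)[1]
  d1 <- (th_end - th_end[1]) %% (2 * pi)
  expect_equal(d1, d0 %% (2 * pi), tolerance = 1e-6)
  # common drift rate
  om <- frequency_correction(sol, w, H)
  drift <- unname((th_end[1] - run$theta[1, 1]) / 500)
  expect_equal(drift, omega0 + eps * om, tolerance = 1e-6)
})

test_that("phase-model relaxation agrees with the closed-form verdicts", {
  fx <- analytic_fixtures(512)
  H <- fx$msin
  Hp <- if_derivative(H)
  lat <- torus_lattice(4, 4)
  w <- coupling_weights(h1 = 1, v1 = 1)
  set.seed(99)
  jitter <- matrix(runif(16, -0.05, 0.05), 4, 4)
  relax <- function(sol) {
    th0 <- unclass(phase_field(sol, lat)) + jitter
    run <- simulate_phase_model(th0, w, H, lat, eps = 0.05, omega = 0.1,
                                duration = 4000)
    th <- run$theta[nrow(run$theta), ]
    obs <- structure(matrix(th %% (2 * pi), 4, 4, byrow = TRUE),
                     class = c("phase_field", "matrix"))
    matches_pattern(obs, phase_field(sol, lat), tol = 0.1)
  }
  # -sin coupling: anti-phase stripe stable, synchrony unstable
  stable <- cluster_solution(2, 1, 2, 1)
  unstable <- cluster_solution()
  expect_identical(classify(eigen_real_parts(stable, w, Hp, lat))$verdict,
                   "stable")
  expect_true(relax(stable))
  expect_identical(classify(eigen_real_parts(unstable, w, Hp, lat))$verdict,
                   "unstable")
  expect_false(relax(unstable))
})

test_that("a 2-cluster biophysical run doubles the population event rate", {
  lc <- table1_lc(256)
  lat <- torus_lattice(6, 6)
  w <- coupling_weights(h1 = 1, v1 = 1)
  conn <- build_connectivity(lat, w)
  sol <- cluster_solution(2, 1, 2, 1)
  st <- init_from_pattern(phase_field(sol, lat), lc, lat)
  run <- simulate_biophysical(st, conn, lc$params, duration = 1200)
  obs <- empirical_phases(run, lat)
  expect_true(matches_pattern(obs, phase_field(sol, lat),
                              tol = 2 * pi * 2 / lc$T))
  # population events: cluster A and cluster B alternate, so the pooled
  # spike train has twice the single-cell rate
  pooled <- sort(unlist(run$spikes))
  pooled <- pooled[pooled > 600]
  events <- cumsum(c(1, diff(pooled) > 5))
  n_events <- max(events)
  cell_rate <- length(run$spikes[[1]][run$spikes[[1]] > 600])
  expect_equal(n_events, 2 * cell_rate, tolerance = 0.1)
})
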