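test_that("controllability Gramian matches closed forms and quadrature", {
  # A = -I: W = (1 - exp(-2T))/2 * I
  W <- controllability_gramian(-diag(2), b = 1, T = 1)
  expect_equal(W, diag(2) * (1 - exp(-2)) / 2, tolerance = 1e-12)

  # quadratic scaling in the control weights
  A <- random_stable_system(5, seed = 11)
  b <- runif(5, 0.5, 2)
  expect_equal(controllability_gramian(A, 3 * b, 1),
               9 * controllability_gramian(A, b, 1), tolerance = 1e-10)

  # independent quadrature oracle on a random stable 6x6
  A6 <- random_stable_system(6, seed = 12)
  b6 <- runif(6, 0.5, 2)
  W6 <- controllability_gramian(A6, b6, T = 1)
  Wq <- gramian_quadrature_oracle(A6, b6, T = 1, npts = 1e5)
  expect_lt(max(abs(W6 - Wq)) / max(abs(W6)), 1e-8)
})

test_that("single-transition energies obey the analytic limits", {
  A <- random_stable_system(4, seed = 21)
  # null transition costs nothing
  r0 <- min_energy_transition(A, 1, rep(0, 4), rep(0, 4))
  expect_equal(r0$global, 0)
  expect_equal(r0$regional, rep(0, 4))

  # 1-region closed form: E = 2/(1 - exp(-2)) for x0=0 -> xf=1, T=1
  r1 <- min_energy_transition(matrix(-1, 1, 1), 1, 0, 1)
  expect_equal(r1$global_closed_form, 2 / (1 - exp(-2)), tolerance = 1e-12)
  expect_equal(r1$global, r1$global_closed_form, tolerance = 1e-6)

  # doubling B quarters the energy, exactly, for the closed form
  set.seed(22)
  x0 <- rnorm(4); xf <- rnorm(4)
  b <- runif(4, 0.5, 2)
  e1 <- min_energy_transition(A, b, x0, xf)
  e2 <- min_energy_transition(A, 2 * b, x0, xf)
  expect_equal(e2$global_closed_form, e1$global_closed_form / 4,
               tolerance = 1e-12)
  expect_gte(min(e1$regional), 0)
})

test_that("the optimal input actually completes the transition", {
  # reachability: integrating the dynamics under u* lands on xf
  for (seed in c(31, 32)) {
    A <- random_stable_system(8, seed = seed)
    set.seed(seed)
    x0 <- rnorm(8); xf <- rnorm(8)
    b <- runif(8, 0.5, 1.5)
    r <- min_energy_transition(A, b, x0, xf, return_input = TRUE)
    xT <- integrate_trajectory(A, b, x0, r$u, r$time)
    expect_lt(sqrt(sum((xT - xf)^2)) / sqrt(sum(xf^2)), 1e-4)
  }
})

test_that("energy time-series matches per-transition computation and scaling laws", {
  cfg <- synth_config(n_regions = 116, n_cortical = 100, n_subjects = 1,
                      n_volumes = 840, injection_volume = 240, seed = 41)
  sc <- gen_connectome(cfg)
  A_s <- stabilize(sc)
  rmap <- gen_receptor_map(cfg)
  bold <- gen_bold(cfg, sc, rmap)
  s <- bold$drug[[1]]
  prof <- energy_timeseries(s, A_s,
                            network_assignment = sc$network_assignment)
  M <- ncol(s$states) - 1
  expect_length(prof$global, M)
  expect_true(all(prof$regional >= 0))
  # internal consistency of the profile
  expect_equal(colSums(prof$regional), prof$global, tolerance = 1e-9)
  expect_equal(colSums(prof$network), prof$global, tolerance = 1e-9)
  # spot-check transitions against the independent grid-quadrature path
  for (k in c(1, 240, 500, 839)) {
    mt <- min_energy_transition(A_s, 1, s$states[, k], s$states[, k + 1])
    expect_equal(prof$global[k], mt$global_closed_form, tolerance = 1e-9)
    expect_equal(prof$regional[, k], mt$regional, tolerance = 1e-5)
  }

  # constant zero series -> zero energy
  z <- state_series(matrix(0, 4, 5))
  A4 <- random_stable_system(4, seed = 42)
  expect_equal(energy_timeseries(z, A4)$global, rep(0, 4))

  # state scaling: energies scale quadratically
  small <- state_series(s$states[1:10, 1:20], injection_volume = 5)
  A10 <- random_stable_system(10, seed = 43)
  p1 <- energy_timeseries(small, A10)
  small2 <- small; small2$states <- 3 * small$states
  p2 <- energy_timeseries(small2, A10)
  expect_equal(p2$global, 9 * p1$global, tolerance = 1e-10)
  expect_equal(p2$regional, 9 * p1$regional, tolerance = 1e-10)

  # B-scaling on the full series: v -> 2v quarters everything
  sch2 <- control_schedule(matrix(2, 10, 19))
  p4 <- energy_timeseries(small, A10, sch2)
  expect_equal(p4$global, p1$global / 4, tolerance = 1e-10)
})

test_that("windowed means implement the drop-partial-window policy", {
  # 838 transitions at TR 2 s -> 27 complete one-minute windows
  x <- rnorm(838)
  w <- windowed_mean(x, 60, 2)
  expect_length(w, 27)
  expect_equal(w[1], mean(x[1:30]))
  expect_equal(w[27], mean(x[781:810]))

  expect_equal(windowed_mean(rep(3.5, 90), 60, 2), rep(3.5, 3))
  expect_equal(windowed_mean(x[1:30], 60, 2), mean(x[1:30]))
  expect_error(windowed_mean(x, 1, 2), "shorter than one TR")
  expect_error(windowed_mean(x, 45, 2), "integer multiple")
})
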