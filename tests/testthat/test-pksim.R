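test_that("compartment simulation conserves mass and equilibrates", {
  # near-bolus into one compartment with (numerically) no elimination:
  # plasma settles at dose/volume
  p1 <- pk_params(n_compartments = 1, volumes = 10, k_elim = 1e-9,
                  k_distribute = numeric(0), ke0 = 0.5, dose_mg = 20,
                  infusion_seconds = 1)
  cs <- simulate_concentration(p1, c(-10, 0, 2, 60, 600))
  expect_equal(cs$plasma[1:2], c(0, 0))
  expect_equal(cs$plasma[3:5], rep(20 / 10 * 1000, 3), tolerance = 1e-5)

  # AUC * clearance = dose (long-horizon quadrature)
  p2 <- pk_params()
  long <- simulate_concentration(p2, seq(0, 8 * 3600, by = 10))
  auc_mg_min <- sum(diff(long$times / 60) *
                      (head(long$plasma, -1) + tail(long$plasma, -1)) / 2) / 1000
  cl <- p2$k_elim * p2$volumes[1]
  expect_equal(auc_mg_min * cl / p2$dose_mg, 1, tolerance = 0.005)

  # instant equilibration limit: effect tracks plasma
  p3 <- pk_params(ke0 = 1e6)
  cs3 <- simulate_concentration(p3, seq(1, 600, by = 1))
  expect_lt(max(abs(cs3$effect - cs3$plasma) / pmax(cs3$plasma, 1e-9)), 0.001)

  expect_error(pk_params(k_elim = -1), "positive")
})

test_that("effect compartment peaks at or after the plasma peak", {
  for (seed in 1:5) {
    set.seed(seed)
    p <- pk_params(volumes = c(runif(1, 5, 30), runif(1, 20, 80)),
                   k_elim = runif(1, 0.05, 0.5),
                   k_distribute = runif(2, 0.05, 0.5),
                   ke0 = runif(1, 0.1, 2))
    cs <- simulate_concentration(p, seq(0, 3600, by = 5))
    expect_gte(which.max(cs$effect), which.max(cs$plasma))
  }
})

test_that("control schedules honor the floor and the degenerate limits", {
  conc <- concentration_series(seq(-100, 500, by = 10),
                               plasma = pmax(0, seq(-100, 500, by = 10)))
  dens <- rgamma(6, 3)
  # alpha = 0: uniform
  s0 <- build_schedule(conc, dens, 0, n_transitions = 20, tr_seconds = 2,
                       injection_volume = 8)
  expect_true(all(s0$v == 1))
  expect_true(s0$uniform)
  # zero concentration, multiplicative mode: uniform
  conc0 <- concentration_series(seq(-100, 500, by = 10),
                                plasma = rep(0, 61))
  sm <- build_schedule(conc0, dens, 5, mode = "multiplicative",
                       n_transitions = 20, tr_seconds = 2,
                       injection_volume = 8)
  expect_true(all(sm$v == 1))
  # uniform density, additive mode: no regional skew
  su <- build_schedule(conc, rep(2.5, 6), 3, n_transitions = 20,
                       tr_seconds = 2, injection_volume = 8)
  expect_true(all(apply(su$v, 2, function(col) length(unique(col)) == 1)))
  # pre-injection columns always uniform; global floor is exactly 1
  sa <- build_schedule(conc, dens, 7, n_transitions = 20, tr_seconds = 2,
                       injection_volume = 8)
  expect_true(all(sa$v[, 1:8] == 1))
  expect_equal(min(sa$v), 1)
  expect_error(build_schedule(conc, dens, -1, n_transitions = 20,
                              tr_seconds = 2, injection_volume = 8),
               "nonnegative")
})

test_that("added control lowers energy monotonically in alpha", {
  st <- small_study(seed = 91, n_subjects = 3, n_volumes = 100,
                    injection_volume = 30, n_regions = 16, n_cortical = 10)
  M <- length(st$placebo_profiles[[1]]$global)
  inj <- 30; tr <- 2
  conc <- simulate_concentration(pk_params(),
                                 seq(-inj * tr, (M - inj) * tr, by = 1))
  post <- (inj + 1):M
  gm_pcb <- colMeans(t(sapply(st$placebo_profiles, `[[`, "global")))
  means <- sapply(c(0, 1, 5, 20, 50), function(a) {
    sch <- build_schedule(conc, st$receptor_maps[[1]], a,
                          n_transitions = M, tr_seconds = tr,
                          injection_volume = inj)
    sim <- simulate_drug_energy(st$bold$placebo, st$A_s, sch)
    mean(sim$group_mean[post])
  })
  # alpha = 0 reproduces the uniform-B placebo energy exactly
  expect_equal(means[1], mean(gm_pcb[post]), tolerance = 1e-12)
  # strictly decreasing in alpha
  expect_true(all(diff(means) < 0))
})

test_that("alpha grid search recovers a self-consistent optimum", {
  st <- small_study(seed = 92, n_subjects = 3, n_volumes = 100,
                    injection_volume = 30, n_regions = 16, n_cortical = 10)
  M <- length(st$placebo_profiles[[1]]$global)
  conc <- simulate_concentration(pk_params(), seq(-60, (M - 30) * 2, by = 1))
  sch20 <- build_schedule(conc, st$receptor_maps[[1]], 20,
                          n_transitions = M, tr_seconds = 2,
                          injection_volume = 30)
  truth <- simulate_drug_energy(st$bold$placebo, st$A_s, sch20)$group_mean
  fit <- fit_alpha_grid(st$bold$placebo, truth, st$A_s, conc,
                        st$receptor_maps[[1]])
  expect_equal(fit$alpha, 20)
  expect_equal(min(fit$distances), 0, tolerance = 1e-8)
  expect_true(all(fit$distances >= 0))
  expect_error(fit_alpha_grid(st$bold$placebo, truth, st$A_s, conc,
                              st$receptor_maps[[1]], grid = numeric(0)),
               "empty")
})

test_that("model comparison prefers the generating variant", {
  st <- small_study(seed = 93, n_subjects = 3, n_volumes = 100,
                    injection_volume = 30, n_regions = 16, n_cortical = 10)
  M <- length(st$placebo_profiles[[1]]$global)
  conc <- simulate_concentration(pk_params(), seq(-60, (M - 30) * 2, by = 1))
  sch <- build_schedule(conc, st$receptor_maps[[1]], 30, source = "effect",
                        n_transitions = M, tr_seconds = 2,
                        injection_volume = 30)
  truth <- simulate_drug_energy(st$bold$placebo, st$A_s, sch)$group_mean
  cmp <- compare_models(st$bold$placebo, truth, st$A_s, conc,
                        st$receptor_maps[[1]],
                        grid = c(10, 20, 30, 40))
  expect_true(all(cmp$distance >= 0))
  best <- cmp$variant[which.min(cmp$distance)]
  expect_equal(best, "effect+receptor")
  expect_error(compare_models(st$bold$placebo, truth, st$A_s, conc,
                              st$receptor_maps[[1]], variants = "bogus"),
               "unknown variant")
})
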