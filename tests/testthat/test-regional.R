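make_profile <- function(reg, tr = 2, inj = 0) {
  structure(list(regional = reg, global = colSums(reg), network = NULL,
                 tr_seconds = tr, injection_volume = inj,
                 subject_id = "s01", condition = "drug"),
            class = "energy_profile")
}

test_that("post/pre change is the relative difference of window means", {
  # 10 regions, 20 pre + 1 crossing + 20 post transitions (injection
  # after volume 21 -> transitions 1..20 pre, 22..41 post)
  set.seed(81)
  pre <- matrix(rgamma(10 * 21, 5), 10, 21)
  post <- pre[, 1:21] * 0.5
  prof <- make_profile(cbind(pre, post[, 1:20]), inj = 21)
  ch <- post_pre_change(prof, window_minutes = 40 / 60)
  # post window means are built from halved pre-window values drawn from
  # the same pool; equal-count truncation keeps 20 transitions per side
  expect_length(ch, 10)

  # exact arithmetic: constant energies
  reg <- cbind(matrix(4, 3, 10), matrix(2, 3, 10))
  prof2 <- make_profile(reg, inj = 10)
  expect_equal(post_pre_change(prof2, window_minutes = 100), rep(-0.5, 3))
  expect_equal(post_pre_change(prof2, window_minutes = 100,
                               relative = FALSE), rep(-2, 3))

  # identical windows give zero change
  reg3 <- cbind(matrix(7, 2, 6), matrix(7, 2, 6))
  expect_equal(post_pre_change(make_profile(reg3, inj = 6),
                               window_minutes = 100), c(0, 0))

  # ratio form is invariant to global rescaling
  prof4 <- make_profile(5 * reg, inj = 10)
  expect_equal(post_pre_change(prof4, window_minutes = 100),
               post_pre_change(prof2, window_minutes = 100))
})

test_that("regional coupling recovers self- and anti-correlation", {
  set.seed(82)
  reg <- matrix(rgamma(6 * 120, 3), 6, 120)
  prof <- make_profile(reg)
  rho <- regional_coupling(prof, reg[3, ])
  expect_equal(rho[3], 1)
  rho_neg <- regional_coupling(prof, -colSums(reg))
  expect_gt(mean(rho_neg < 0), 0.5)

  # windowed variant aligns to the per-minute grid
  rho_w <- regional_coupling(prof, rnorm(4), windowed = TRUE)
  expect_length(rho_w, 6)
  expect_error(regional_coupling(prof, 1:2), "length mismatch")
})

test_that("delta series is plain elementwise difference", {
  a <- rnorm(10); b <- rnorm(10)
  expect_equal(delta_series(a, a), rep(0, 10))
  expect_equal(delta_series(a, rep(0, 10)), a)
  expect_equal(delta_series(a + 3, b), delta_series(a, b) + 3)
  expect_error(delta_series(a, b[1:5]), "mismatch")
})

test_that("receptor association delegates exactly to the spin test", {
  set.seed(83)
  n_cx <- 40
  coords <- matrix(rnorm(n_cx * 3), n_cx, 3)
  coords <- coords / sqrt(rowSums(coords^2))
  nulls <- build_spin_nulls(coords, 100, seed = 7)
  dens <- c(rgamma(n_cx, 3), rgamma(8, 3))
  rmap <- receptor_map(dens, cortical_mask = c(rep(TRUE, n_cx),
                                               rep(FALSE, 8)))
  # metric equal to the density: rho = 1; negated ranks: rho = -1
  expect_equal(receptor_association(dens, rmap, nulls)$rho, 1)
  m2 <- dens; m2[rmap$cortical_mask] <- -rank(dens[rmap$cortical_mask])
  expect_equal(receptor_association(m2, rmap, nulls)$rho, -1)

  metric <- rnorm(48)
  ra <- receptor_association(metric, rmap, nulls, include_subcortex = TRUE)
  st <- spin_test(metric[1:n_cx], dens[1:n_cx], nulls)
  expect_identical(ra$rho, st$rho)
  expect_identical(ra$p_spin, st$p_spin)
  expect_equal(ra$rho_all, cor(rank(metric), rank(dens)))
  expect_error(receptor_association(metric[1:10], rmap, nulls), "mismatch")
})

test_that("half-period t summaries localize planted effects and antisymmetrize", {
  set.seed(84)
  n_sub <- 6; M <- 40; inj <- 10
  mk <- function(shift_first_half) {
    lapply(seq_len(n_sub), function(s) {
      net <- matrix(rgamma(2 * M, 20), 2, M,
                    dimnames = list(c("Vis", "Default"), NULL))
      if (shift_first_half) net["Vis", 11:25] <- net["Vis", 11:25] + 15
      structure(list(global = colSums(net), regional = NULL, network = net,
                     tr_seconds = 2, injection_volume = inj),
                class = "energy_profile")
    })
  }
  a <- mk(TRUE); b <- mk(FALSE)
  tt <- halfperiod_tstats(a, b)
  vis1 <- tt$mean_t[tt$network == "Vis" & tt$half == "first"]
  vis2 <- tt$mean_t[tt$network == "Vis" & tt$half == "second"]
  expect_gt(abs(vis1), abs(vis2))

  flipped <- halfperiod_tstats(b, a)
  expect_equal(flipped$mean_t, -tt$mean_t)

  same <- halfperiod_tstats(b, b)
  expect_true(all(is.na(same$mean_t) | same$mean_t == 0))
})
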