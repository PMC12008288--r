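test_that("cluster test finds planted effects and nothing under identity", {
  set.seed(71)
  a <- matrix(rnorm(14 * 300), 14, 300)

  r0 <- paired_cluster_test(a, a, n_perm = 200, seed = 1)
  expect_equal(nrow(r0$clusters), 0)
  expect_false(any(r0$significant_mask))

  b <- a
  b[, 100:200] <- b[, 100:200] + 5 +
    matrix(rnorm(14 * 101, sd = 0.5), 14, 101)
  r1 <- paired_cluster_test(b, a, n_perm = 500, seed = 1)
  sig <- r1$clusters[r1$clusters$p <= 0.05, ]
  expect_equal(nrow(sig), 1)
  expect_lte(sig$start, 100)
  expect_gte(sig$end, 200)
  expect_true(all(r1$significant_mask[100:200]))

  # swapping conditions flips the sign of the statistic exactly
  r2 <- paired_cluster_test(a, b, n_perm = 500, seed = 1)
  expect_equal(r2$point_stats, -r1$point_stats)
  expect_equal(r2$clusters$mass, -r1$clusters$mass)

  expect_error(paired_cluster_test(a, a[, 1:10]), "equal shapes")
  expect_error(paired_cluster_test(a * NA, a), "NaN")
})

test_that("permutation Spearman behaves at the extremes and under covariates", {
  r <- perm_spearman(1:10, 1:10, n_perm = 999, seed = 1)
  expect_equal(r$rho, 1)
  expect_equal(r$p_perm, 1 / 1000)

  # residualizing on y itself removes all shared variance
  set.seed(72)
  x <- rnorm(50); y <- rnorm(50)
  rc <- perm_spearman(x, y, n_perm = 500, seed = 1, covariate = y)
  expect_lt(abs(rc$rho), 0.05)

  # invariance to strictly monotone transforms
  set.seed(73)
  x <- runif(40); y <- x + rnorm(40, sd = 0.3)
  r1 <- perm_spearman(x, y, n_perm = 500, seed = 9)
  r2 <- perm_spearman(exp(3 * x), y^3 + 10, n_perm = 500, seed = 9)
  expect_equal(r1$rho, r2$rho)
  expect_equal(r1$p_perm, r2$p_perm)

  expect_error(perm_spearman(rep(1, 10), 1:10), "constant")
})

test_that("BH correction reproduces the hand-computed step-up", {
  expect_equal(bh_correct(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_correct(0.2), 0.2)
  expect_equal(bh_correct(rep(1, 5)), rep(1, 5))
  expect_error(bh_correct(c(0.5, 1.2)), "out of")
})

test_that("spin nulls preserve constant maps and the value multiset when bijective", {
  set.seed(74)
  coords <- matrix(rnorm(60 * 3), 60, 3)
  coords <- coords / sqrt(rowSums(coords^2))
  nulls <- build_spin_nulls(coords, n_spins = 50, seed = 5)
  expect_equal(dim(nulls$permutations), c(50, 60))
  expect_true(all(nulls$permutations >= 1 & nulls$permutations <= 60))

  cmap <- rep(4.2, 60)
  for (s in 1:50) expect_equal(cmap[nulls$permutations[s, ]], cmap)

  vmap <- rnorm(60)
  for (s in 1:50) {
    p <- nulls$permutations[s, ]
    if (length(unique(p)) == 60) {
      expect_equal(sort(vmap[p]), sort(vmap))
    }
  }
  expect_error(build_spin_nulls(coords * 2, 10), "unit sphere")
})

test_that("spin test is exact on self-correlation and guards autocorrelation", {
  set.seed(75)
  coords <- matrix(rnorm(80 * 3), 80, 3)
  coords <- coords / sqrt(rowSums(coords^2))
  nulls <- build_spin_nulls(coords, n_spins = 300, seed = 6)

  m <- rnorm(80)
  st <- spin_test(m, m, nulls)
  expect_equal(st$rho, 1)

  # two smooth maps sharing a spatial gradient: the spin p must exceed the
  # naive permutation p (spatial autocorrelation inflates naive significance)
  grad <- coords[, 1]
  set.seed(76)
  m1 <- grad + 0.4 * rnorm(80)
  m2 <- grad + 0.4 * rnorm(80)
  st2 <- spin_test(m1, m2, nulls)
  naive <- perm_spearman(m1, m2, n_perm = 300, seed = 6)
  expect_gt(st2$p_spin, naive$p_perm)

  expect_error(spin_test(m[1:10], m[1:10], nulls), "does not match")
})

test_that("dominance analysis decomposes variance as hand enumeration dictates", {
  set.seed(77)
  # single predictor takes all the importance
  x <- rnorm(40); y <- 2 * x + rnorm(40)
  d1 <- dominance_analysis(matrix(x, ncol = 1), y)
  expect_equal(unname(d1$importance_pct), 100)

  # two exactly orthogonal predictors with marginal R^2 0.3 and 0.1:
  # hand enumeration of the 3 submodels gives importances 75% / 25%
  n <- 24
  raw <- qr.Q(qr(cbind(1, matrix(rnorm(n * 3), n, 3))))[, 2:4]
  y2 <- sqrt(0.3) * raw[, 1] + sqrt(0.1) * raw[, 2] + sqrt(0.6) * raw[, 3]
  d2 <- dominance_analysis(raw[, 1:2], y2)
  expect_equal(unname(d2$importance_pct), c(75, 25), tolerance = 1e-9)
  expect_equal(d2$r2_full, 0.4, tolerance = 1e-12)

  # p = 5 -> 31 submodels; importances sum to 100 within 1e-9
  X5 <- matrix(rnorm(60 * 5), 60, 5)
  y5 <- X5 %*% runif(5) + rnorm(60)
  d5 <- dominance_analysis(X5, y5)
  expect_equal(d5$n_submodels, 31)
  expect_equal(sum(d5$importance_pct), 100, tolerance = 1e-9)
  expect_true(all(d5$total_dominance > -1e-12))

  expect_error(dominance_analysis(cbind(x, x), y), "singular")
})

test_that("stochastic procedures are reproducible under a fixed seed", {
  set.seed(78)
  a <- matrix(rnorm(8 * 100), 8, 100)
  b <- a + matrix(rnorm(8 * 100, sd = 0.5), 8, 100)
  r1 <- paired_cluster_test(a, b, n_perm = 200, seed = 99)
  r2 <- paired_cluster_test(a, b, n_perm = 200, seed = 99)
  expect_identical(r1, r2)

  coords <- matrix(rnorm(30 * 3), 30, 3)
  coords <- coords / sqrt(rowSums(coords^2))
  expect_identical(build_spin_nulls(coords, 20, seed = 3),
                   build_spin_nulls(coords, 20, seed = 3))
  x <- rnorm(20); y <- rnorm(20)
  expect_identical(perm_spearman(x, y, 100, seed = 4),
                   perm_spearman(x, y, 100, seed = 4))
})
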