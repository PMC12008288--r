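# Independent oracles used across the suite. These deliberately avoid the
# package's computational paths (block matrix exponential, spectral
# formulas) so agreement is a genuine cross-check.

# LZ76 exhaustive-history parse by direct longest-reproducible-prefix
# search (O(n^3) substring scan, overlap allowed; final word may be
# non-exhaustive).
lz76_oracle <- function(b) {
  if (is.character(b)) b <- as.integer(strsplit(b, "")[[1]])
  s <- paste(b, collapse = "")
  n <- nchar(s)
  cnt <- 0L
  p <- 1L
  while (p <= n) {
    k <- 0L
    while (p + k <= n) {
      sub <- substr(s, p, p + k)
      found <- FALSE
      if (p > 1L) {
        for (i in 1:(p - 1L)) {
          if (substr(s, i, i + k) == sub) { found <- TRUE; break }
        }
      }
      if (found) k <- k + 1L else break
    }
    cnt <- cnt + 1L
    p <- p + min(k + 1L, n - p + 1L)
  }
  cnt
}

# Minimum energy by brute force: exact zero-order-hold discretization of
# the dynamics (Delta t = T/steps) and the least-norm input sequence
# satisfying the endpoint constraint. Energy = sum u'u * dt.
min_energy_discrete_oracle <- function(A, b, x0, xf, T = 1, steps = 2000) {
  n <- nrow(A)
  dt <- T / steps
  Ad <- as.matrix(Matrix::expm(Matrix::Matrix(A * dt)))
  # Bd = int_0^dt exp(A s) B ds via augmented exponential
  B <- diag(rep_len(b, n), n)
  Aug <- rbind(cbind(A, B), matrix(0, n, 2 * n))
  E <- as.matrix(Matrix::expm(Matrix::Matrix(Aug * dt)))
  Bd <- E[1:n, (n + 1):(2 * n), drop = FALSE]
  # S = sum_k M_k M_k', M_k = Ad^{K-1-k} Bd; energy = dt * d' S^{-1} d
  S <- matrix(0, n, n)
  P <- diag(n)
  AdK <- diag(n)
  for (k in seq_len(steps)) {
    Mk <- P %*% Bd
    S <- S + Mk %*% t(Mk)
    P <- Ad %*% P
    AdK <- Ad %*% AdK
  }
  d <- xf - as.numeric(AdK %*% x0)
  dt * sum(d * solve(S, d))
}

# Gramian by trapezoidal quadrature of the integrand, propagators from a
# plain eigendecomposition (not the Van Loan block form).
gramian_quadrature_oracle <- function(A, b, T = 1, npts = 1e5) {
  n <- nrow(A)
  e <- eigen(A)
  Vi <- solve(e$vectors)
  BBt <- diag(rep_len(b, n)^2, n)
  ts <- seq(0, T, length.out = npts)
  dt <- ts[2] - ts[1]
  W <- matrix(0, n, n)
  for (i in seq_along(ts)) {
    Es <- Re(e$vectors %*% (exp(e$values * ts[i]) * Vi))
    Q <- Es %*% BBt %*% t(Es)
    w <- if (i == 1 || i == npts) 0.5 else 1
    W <- W + w * Q
  }
  W * dt
}

# RK4 integration of xdot = A x + B u(t) with u given on a uniform grid
# (linear interpolation between grid points).
integrate_trajectory <- function(A, b, x0, u, tg) {
  n <- length(x0)
  B <- diag(rep_len(b, n), n)
  uf <- function(t) {
    apply(u, 1, function(ui) stats::approx(tg, ui, xout = t, rule = 2)$y)
  }
  x <- x0
  for (k in seq_len(length(tg) - 1)) {
    h <- tg[k + 1] - tg[k]
    f <- function(t, xx) as.numeric(A %*% xx + B %*% uf(t))
    k1 <- f(tg[k], x)
    k2 <- f(tg[k] + h / 2, x + h / 2 * k1)
    k3 <- f(tg[k] + h / 2, x + h / 2 * k2)
    k4 <- f(tg[k + 1], x + h * k3)
    x <- x + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  x
}

# random stable symmetric system of size n (via the package-independent
# construction: symmetric nonnegative weights, explicit eigen-shift)
random_stable_system <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  w <- matrix(stats::runif(n * n), n, n)
  w <- (w + t(w)) / 2
  diag(w) <- 0
  lmax <- max(eigen(w, symmetric = TRUE, only.values = TRUE)$values)
  w / (lmax + 1) - diag(n)
}

# small synthetic study used by several tests (kept light on purpose)
small_study <- function(seed = 1, beta = 0.35, gamma = 0.8,
                        n_regions = 32, n_cortical = 22, n_subjects = 8,
                        n_volumes = 180, injection_volume = 60) {
  cfg <- synth_config(n_regions = n_regions, n_cortical = n_cortical,
                      n_subjects = n_subjects, n_volumes = n_volumes,
                      injection_volume = injection_volume,
                      beta = beta, gamma = gamma, seed = seed)
  synth_study(cfg)
}

# Moran's I with inverse-distance weights (spatial autocorrelation check)
morans_i <- function(values, coords) {
  n <- length(values)
  d <- as.matrix(stats::dist(coords))
  w <- 1 / d
  diag(w) <- 0
  z <- values - mean(values)
  (n / sum(w)) * sum(w * outer(z, z)) / sum(z^2)
}
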