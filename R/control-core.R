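#' Regional BOLD state sequence for one scan
#'
#' @param states N x V numeric matrix: regions in rows, volumes in columns.
#' @param tr_seconds repetition time in seconds (default 2).
#' @param injection_volume number of pre-injection volumes; volumes
#'   `1:injection_volume` precede the injection, volume
#'   `injection_volume + 1` is the first post-injection volume. Use 0 for a
#'   scan with no injection.
#' @param subject_id,condition metadata strings; `condition` is typically
#'   "drug" or "placebo".
#' @return object of class `state_series`
#' @export
state_series <- function(states, tr_seconds = 2,
                         injection_volume = 0,
                         subject_id = "s01", condition = "placebo") {
  states <- as.matrix(states)
  storage.mode(states) <- "double"
  if (ncol(states) < 2) stop("need at least 2 volumes")
  if (any(!is.finite(states))) stop("non-finite entries in states")
  if (injection_volume < 0 || injection_volume >= ncol(states)) {
    stop("injection_volume out of range")
  }
  structure(
    list(states = states, tr_seconds = tr_seconds,
         injection_volume = as.integer(injection_volume),
         subject_id = subject_id, condition = condition),
    class = "state_series")
}

#' @export
print.state_series <- function(x, ...) {
  cat("state_series:", nrow(x$states), "regions x", ncol(x$states),
      "volumes | TR =", x$tr_seconds, "s | injection after volume",
      x$injection_volume, "|", x$subject_id, "/", x$condition, "\n")
  invisible(x)
}

#' Control schedule: per-transition diagonal control weights
#'
#' Column k holds the diagonal of the input matrix B used for transition k
#' (from volume k to volume k+1). The uniform strategy (all ones) is the
#' identity-B control used for all empirical energy calculations.
#'
#' @param v N x M matrix of strictly positive weights, or the string
#'   "uniform" together with `n_regions`/`n_transitions`.
#' @param n_regions,n_transitions dimensions when `v = "uniform"`.
#' @return object of class `control_schedule` with elements `v`, `uniform`.
#' @export
control_schedule <- function(v, n_regions = NULL, n_transitions = NULL) {
  if (identical(v, "uniform")) {
    v <- matrix(1, n_regions, n_transitions)
  }
  v <- as.matrix(v)
  if (any(!is.finite(v)) || any(v <= 0)) {
    stop("control weights must be strictly positive and finite")
  }
  structure(list(v = v, uniform = all(v == 1)), class = "control_schedule")
}

#' Control computation settings
#'
#' @param T time horizon for each transition (default 1, the conventional
#'   choice for adjacent-volume transitions).
#' @param integration_steps odd number of grid points (>= 3) used when the
#'   optimal input trajectory is integrated explicitly (default 1001).
#' @export
control_config <- function(T = 1, integration_steps = 1001L) {
  if (T <= 0) stop("time horizon T must be positive")
  integration_steps <- as.integer(integration_steps)
  if (integration_steps < 3L || integration_steps %% 2L == 0L) {
    stop("integration_steps must be odd and >= 3")
  }
  structure(list(T = T, integration_steps = integration_steps),
            class = "control_config")
}

# dense matrix exponential (Matrix::expm on a base matrix)
ce_expm <- function(m) {
  as.matrix(Matrix::expm(Matrix::Matrix(m, sparse = FALSE)))
}

# coerce a system_matrix / bare matrix to a plain matrix
as_dyn_matrix <- function(A_s) {
  if (inherits(A_s, "system_matrix")) A_s$A else as.matrix(A_s)
}

#' Controllability Gramian over a finite horizon
#'
#' Computes `W_T = integral_0^T exp(A s) B B' exp(A' s) ds` with
#' `B = diag(b)`, via the Van Loan block matrix-exponential identity: a
#' single exponential of the 2N x 2N block matrix `[[-A, BB'], [0, A']]`
#' yields both `exp(A'T)` and the Gramian, avoiding quadrature error.
#'
#' @param A_s stable dynamics matrix (`system_matrix` or plain matrix).
#' @param b strictly positive control-weight vector (scalar recycled).
#' @param T time horizon.
#' @return symmetric positive-definite N x N matrix.
#' @export
controllability_gramian <- function(A_s, b = 1, T = 1) {
  A <- as_dyn_matrix(A_s)
  n <- nrow(A)
  b <- rep_len(as.numeric(b), n)
  if (any(b <= 0)) stop("control weights b must be strictly positive")
  Q <- diag(b^2, n)    # B B' for diagonal B
  C <- rbind(cbind(-A, Q),
             cbind(matrix(0, n, n), t(A)))
  E <- ce_expm(C * T)
  F3 <- E[(n + 1):(2 * n), (n + 1):(2 * n), drop = FALSE]  # exp(A'T)
  G2 <- E[1:n, (n + 1):(2 * n), drop = FALSE]
  W <- t(F3) %*% G2
  W <- (W + t(W)) / 2
  kap <- kappa(W, exact = FALSE)
  if (is.finite(kap) && kap > 1e12) {
    warning("Gramian condition number ", format(kap, digits = 3),
            " exceeds 1e12; proceeding with symmetric solve")
  }
  W
}

# spectral Gramian for symmetric A: W = U ((U'BB'U) o K) U'
# K_jl = (exp((l_j + l_l) T) - 1) / (l_j + l_l); requires all l < 0 pairs sums != 0
gramian_spectral <- function(U, lam, b, T) {
  S <- outer(lam, lam, "+")
  K <- (exp(S * T) - 1) / S
  M <- crossprod(U * b)          # U' diag(b^2) U
  U %*% (M * K) %*% t(U)
}

# propagator helpers for a general (possibly non-symmetric) stable A
eig_general <- function(A) {
  if (max(abs(A - t(A))) < 1e-12) {
    e <- eigen(A, symmetric = TRUE)
    list(values = e$values, vectors = e$vectors,
         vinv = t(e$vectors), symmetric = TRUE)
  } else {
    e <- eigen(A)
    list(values = e$values, vectors = e$vectors,
         vinv = solve(e$vectors), symmetric = FALSE)
  }
}

expAt <- function(eg, t) {
  M <- eg$vectors %*% (exp(eg$values * t) * eg$vinv)
  if (eg$symmetric) M else Re(M)
}

#' Minimum control energy for a single state transition
#'
#' Solves the minimum-input problem for the linear system
#' `xdot = A x + B u` driving `x0` to `xf` over horizon `T`: the optimal
#' input is `u*(t) = B' exp(A'(T - t)) W_T^{-1} (xf - exp(A T) x0)`.
#' Regional energies integrate `u_i*(t)^2` over the horizon on a trapezoidal
#' grid; the global energy is their sum and matches the closed form
#' `d' W_T^{-1} d`.
#'
#' @inheritParams controllability_gramian
#' @param x0,xf initial and final state vectors.
#' @param cfg a [control_config()].
#' @param return_input also return the optimal input trajectory `u` (N x
#'   grid) and the time grid (for trajectory/reachability checks).
#' @return list with `regional` (length-N vector), `global` (scalar),
#'   `global_closed_form` (d' W^{-1} d); plus `u`, `time` if requested.
#' @export
min_energy_transition <- function(A_s, b = 1, x0, xf, cfg = control_config(),
                                  return_input = FALSE) {
  A <- as_dyn_matrix(A_s)
  n <- nrow(A)
  b <- rep_len(as.numeric(b), n)
  x0 <- as.numeric(x0); xf <- as.numeric(xf)
  if (any(!is.finite(x0)) || any(!is.finite(xf))) stop("non-finite states")
  T <- cfg$T
  eg <- eig_general(A)
  d <- xf - as.numeric(expAt(eg, T) %*% x0)
  W <- controllability_gramian(A, b, T)
  z <- tryCatch(solve(W, d), error = function(e) stop("singular Gramian"))
  closed <- sum(d * z)
  # u(t) = B' exp(A'(T-t)) z ; exp(A's) z = t(Vinv) (exp(lam s) * (t(V) z))
  tg <- seq(0, T, length.out = cfg$integration_steps)
  c0 <- as.numeric(crossprod(eg$vectors, z))
  Egrid <- exp(outer(eg$values, T - tg))         # N x G (possibly complex)
  Uu <- t(eg$vinv) %*% (Egrid * c0)
  u <- b * Re(Uu)
  dt <- tg[2] - tg[1]
  u2 <- u^2
  regional <- dt * (rowSums(u2) - (u2[, 1] + u2[, ncol(u2)]) / 2)
  out <- list(regional = regional, global = sum(regional),
              global_closed_form = closed)
  if (return_input) {
    out$u <- u
    out$time <- tg
  }
  out
}

# vectorized minimum-energy engine over explicit (x0, xf) column pairs.
# For symmetric A regional energies use the exact spectral identity
#   E_i = b_i^2 [U (K o (c c')) U']_ii,  c = U' W^{-1} d,
#   K_jl = (exp((l_j + l_l) T) - 1)/(l_j + l_l)
# (the integral of u_i*(t)^2 in closed form); Gramians are factorized once
# per unique schedule column. Non-symmetric A falls back to per-transition
# trajectory integration.
energy_pairs <- function(X0, Xf, A_s, v, cfg, regional = TRUE) {
  n <- nrow(X0); M <- ncol(X0)
  T <- cfg$T
  A <- as_dyn_matrix(A_s)
  symmetric <- max(abs(A - t(A))) < 1e-12
  if (!symmetric) {
    reg <- if (regional) matrix(0, n, M) else NULL
    glob <- numeric(M)
    for (k in seq_len(M)) {
      r <- min_energy_transition(A, v[, k], X0[, k], Xf[, k], cfg)
      glob[k] <- r$global_closed_form
      if (regional) reg[, k] <- r$regional
    }
    return(list(global = glob, regional = reg))
  }
  if (inherits(A_s, "system_matrix")) {
    U <- A_s$evectors; lam <- A_s$evalues
  } else {
    e <- eigen(A, symmetric = TRUE); U <- e$vectors; lam <- e$values
  }
  Ssum <- outer(lam, lam, "+")
  K <- (exp(Ssum * T) - 1) / Ssum
  eAT <- U %*% (exp(lam * T) * t(U))
  D <- Xf - eAT %*% X0
  glob <- numeric(M)
  reg <- if (regional) matrix(0, n, M) else NULL
  key <- apply(v, 2, function(col) paste(col, collapse = "\r"))
  for (g in split(seq_len(M), key)) {
    b <- v[, g[1]]
    W <- gramian_spectral(U, lam, b, T)
    ch <- chol((W + t(W)) / 2)
    Dk <- D[, g, drop = FALSE]
    Z <- backsolve(ch, forwardsolve(t(ch), Dk))
    glob[g] <- colSums(Dk * Z)
    if (regional) {
      Cz <- crossprod(U, Z)
      b2 <- b^2
      for (j in seq_along(g)) {
        S <- K * tcrossprod(Cz[, j])
        reg[, g[j]] <- b2 * rowSums((U %*% S) * U)
      }
    }
  }
  list(global = glob, regional = reg)
}

#' Control energy time-series over a BOLD state sequence
#'
#' Treats every pair of adjacent volumes as a state transition (`x0` =
#' volume k, `xf` = volume k+1) and computes minimum control energy per
#' region, per network, and globally for each transition. With a uniform
#' schedule the Gramian is computed once and reused across transitions.
#'
#' For the symmetric operators produced by [stabilize()] regional energies
#' are evaluated by an exact spectral formula (no quadrature error);
#' otherwise each transition falls back to [min_energy_transition()].
#'
#' @param series a [state_series()].
#' @param A_s a [stabilize()] result (or stable matrix).
#' @param schedule a [control_schedule()] with V-1 columns, or NULL for
#'   uniform control.
#' @param cfg a [control_config()].
#' @param network_assignment optional character vector (length N) of network
#'   names used to fill the network-level rows.
#' @param regional if FALSE, skip per-region/network energies (fast path for
#'   global-only analyses such as the alpha grid search).
#' @return object of class `energy_profile`: list with `regional`
#'   (N x V-1 or NULL), `global` (length V-1), `network`
#'   (networks x V-1 or NULL), plus `tr_seconds`, `injection_volume`,
#'   `subject_id`, `condition`.
#' @export
energy_timeseries <- function(series, A_s, schedule = NULL,
                              cfg = control_config(),
                              network_assignment = NULL,
                              regional = TRUE) {
  X <- series$states
  n <- nrow(X); V <- ncol(X); M <- V - 1L
  if (is.null(schedule)) {
    schedule <- control_schedule("uniform", n_regions = n, n_transitions = M)
  }
  v <- schedule$v
  if (nrow(v) != n || ncol(v) != M) {
    stop("schedule must be ", n, " x ", M, ", got ",
         nrow(v), " x ", ncol(v))
  }
  ep <- energy_pairs(X[, 1:M, drop = FALSE], X[, 2:V, drop = FALSE],
                     A_s, v, cfg, regional)
  glob <- ep$global; reg <- ep$regional
  net <- NULL
  if (regional && !is.null(network_assignment)) {
    nets <- unique(network_assignment)
    net <- t(vapply(nets, function(nm) {
      colSums(reg[network_assignment == nm, , drop = FALSE])
    }, numeric(M)))
    rownames(net) <- nets
  }
  structure(
    list(regional = reg, global = glob, network = net,
         tr_seconds = series$tr_seconds,
         injection_volume = series$injection_volume,
         subject_id = series$subject_id, condition = series$condition),
    class = "energy_profile")
}

#' @export
print.energy_profile <- function(x, ...) {
  cat("energy_profile:", length(x$global), "transitions",
      if (!is.null(x$regional)) paste("|", nrow(x$regional), "regions"),
      "| mean global E =", format(mean(x$global), digits = 4), "\n")
  invisible(x)
}

#' Average an energy time-series over fixed-length windows
#'
#' Non-overlapping windows of `window_seconds` (an integer multiple of the
#' TR); a trailing partial window is dropped. One-minute windows align the
#' energy series with per-minute subjective intensity ratings.
#'
#' @param x an `energy_profile` or a plain numeric vector on the transition
#'   grid.
#' @param window_seconds window length in seconds (default 60).
#' @param tr_seconds repetition time; taken from the profile if available.
#' @return for a vector: vector of window means. For an `energy_profile`:
#'   list with `global` (vector), `regional` (N x n_windows or NULL).
#' @export
windowed_mean <- function(x, window_seconds = 60, tr_seconds = NULL) {
  if (inherits(x, "energy_profile")) {
    tr <- if (is.null(tr_seconds)) x$tr_seconds else tr_seconds
    g <- windowed_mean(x$global, window_seconds, tr)
    r <- if (!is.null(x$regional)) {
      t(apply(x$regional, 1, windowed_mean,
              window_seconds = window_seconds, tr_seconds = tr))
    }
    return(list(global = g, regional = r))
  }
  if (is.null(tr_seconds)) stop("tr_seconds required for plain vectors")
  if (window_seconds < tr_seconds) stop("window shorter than one TR")
  wpt <- window_seconds / tr_seconds
  if (abs(wpt - round(wpt)) > 1e-9) {
    stop("window must be an integer multiple of the TR")
  }
  wpt <- as.integer(round(wpt))
  nw <- length(x) %/% wpt
  if (nw == 0L) stop("series shorter than one window")
  colMeans(matrix(x[seq_len(nw * wpt)], nrow = wpt))
}
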