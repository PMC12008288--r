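#' Cluster-based paired permutation test over time
#'
#' Per-time-point paired t statistics on `a - b` are thresholded at the
#' two-tailed t critical value for `alpha`; maximal supra-threshold runs
#' (separately for positive and negative excursions) form clusters whose
#' mass is the sum of t within the run. The null distribution is the maximum
#' absolute cluster mass over random per-subject sign flips of the paired
#' differences; cluster p-values use the add-one convention
#' `(1 + #[null >= mass]) / (1 + n_perm)`.
#'
#' @param a,b subjects x time matrices (paired observations).
#' @param alpha cluster-forming and cluster-level significance threshold.
#' @param n_perm number of sign-flip permutations.
#' @param seed optional integer seed for reproducibility.
#' @return object of class `cluster_result`: `point_stats` (t per time
#'   point), `clusters` (data.frame start/end/mass/p), `significant_mask`
#'   (logical per time point), `threshold`.
#' @export
paired_cluster_test <- function(a, b, alpha = 0.05, n_perm = 1000,
                                seed = NULL) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (!all(dim(a) == dim(b))) stop("a and b must have equal shapes")
  if (nrow(a) < 2) stop("need at least 2 subjects")
  if (any(is.na(a)) || any(is.na(b))) stop("NaN/NA in input")
  if (n_perm < 100) warning("n_perm < 100: cluster p-values will be coarse")
  if (!is.null(seed)) set.seed(seed)
  d <- a - b
  ns <- nrow(d); nt <- ncol(d)
  thr <- stats::qt(1 - alpha / 2, df = ns - 1)

  tstat <- function(x) {
    m <- colMeans(x)
    s <- sqrt(pmax((colSums(x^2) - ns * m^2) / (ns - 1), 0))
    tv <- m / (s / sqrt(ns))
    tv[is.nan(tv)] <- 0     # all-zero differences carry no signal
    tv
  }
  find_clusters <- function(tv) {
    out <- list()
    for (sgn in c(1, -1)) {
      supra <- sgn * tv > thr
      if (!any(supra)) next
      r <- rle(supra)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      for (j in which(r$values)) {
        out[[length(out) + 1L]] <-
          c(start = starts[j], end = ends[j],
            mass = sum(tv[starts[j]:ends[j]]))
      }
    }
    out
  }

  t_obs <- tstat(d)
  cl <- find_clusters(t_obs)
  null_max <- numeric(n_perm)
  for (p in seq_len(n_perm)) {
    flips <- sample(c(-1, 1), ns, replace = TRUE)
    tp <- tstat(flips * d)
    cp <- find_clusters(tp)
    null_max[p] <- if (length(cp)) max(abs(vapply(cp, `[[`, 0, "mass")))
                   else 0
  }
  mask <- rep(FALSE, nt)
  clusters <- data.frame(start = integer(), end = integer(),
                         mass = numeric(), p = numeric())
  for (ci in cl) {
    pval <- (1 + sum(null_max >= abs(ci["mass"]))) / (1 + n_perm)
    clusters <- rbind(clusters,
                      data.frame(start = ci[["start"]], end = ci[["end"]],
                                 mass = ci[["mass"]], p = pval))
    if (pval <= alpha) mask[ci[["start"]]:ci[["end"]]] <- TRUE
  }
  structure(list(point_stats = t_obs, clusters = clusters,
                 significant_mask = mask, threshold = thr),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat("cluster_result:", nrow(x$clusters), "cluster(s),",
      sum(x$significant_mask), "significant time-point(s)\n")
  if (nrow(x$clusters)) print(x$clusters)
  invisible(x)
}

#' Permutation Spearman correlation (optional covariate control)
#'
#' Spearman rank correlation with a permutation p-value using the add-one
#' convention over random permutations of `y`. With a covariate, `x` and `y`
#' are rank-transformed and residualized on the ranked covariate by least
#' squares before correlating (rank partial correlation); permutations act
#' on the residualized `y`.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @param n_perm number of permutations (default 10000).
#' @param seed optional seed.
#' @param covariate optional numeric vector (e.g. framewise displacement).
#' @return list with `rho` and `p_perm` (two-sided).
#' @export
perm_spearman <- function(x, y, n_perm = 10000, seed = NULL,
                          covariate = NULL) {
  if (length(x) != length(y)) stop("length mismatch")
  n <- length(x)
  if (n < 3) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("constant input: ranks undefined")
  }
  if (!is.null(seed)) set.seed(seed)
  rx <- rank(x); ry <- rank(y)
  if (!is.null(covariate)) {
    rc <- cbind(1, rank(covariate))
    P <- diag(n) - rc %*% solve(crossprod(rc), t(rc))
    rx0 <- rx; ry0 <- ry
    rx <- as.numeric(P %*% rx)
    ry <- as.numeric(P %*% ry)
    # residual variance at rounding-noise level: nothing left to correlate
    if (sum(rx^2) < 1e-10 * sum((rx0 - mean(rx0))^2) ||
        sum(ry^2) < 1e-10 * sum((ry0 - mean(ry0))^2)) {
      return(list(rho = 0, p_perm = 1))
    }
  }
  rho <- stats::cor(rx, ry)
  rxc <- rx - mean(rx); ryc <- ry - mean(ry)
  denom <- sqrt(sum(rxc^2) * sum(ryc^2))
  null <- vapply(seq_len(n_perm), function(i) {
    sum(rxc * ryc[sample.int(n)]) / denom
  }, numeric(1))
  p <- (1 + sum(abs(null) >= abs(rho))) / (1 + n_perm)
  list(rho = rho, p_perm = p)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Thin wrapper over `stats::p.adjust(method = "BH")` with range checking.
#'
#' @param pvals numeric vector of p-values in \[0, 1\].
#' @export
bh_correct <- function(pvals) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE)) stop("p-values out of [0,1]")
  stats::p.adjust(pvals, method = "BH")
}

#' Build spin-permutation nulls for cortical maps
#'
#' Applies `n_spins` uniform random 3D rotations to parcel centroids on the
#' unit sphere and reassigns each parcel to the nearest rotated parcel
#' (greedy nearest neighbour; duplicate assignments allowed). Spun maps keep
#' the spatial autocorrelation of the original but randomize its anatomical
#' alignment.
#'
#' @param coords N_cortex x 3 matrix of unit-sphere centroids.
#' @param n_spins number of rotations.
#' @param seed optional seed.
#' @return object of class `spin_nulls`: `permutations` (n_spins x N
#'   integer matrix; row s maps parcel i to source parcel
#'   `permutations[s, i]`), `coords`.
#' @export
build_spin_nulls <- function(coords, n_spins = 10000, seed = NULL) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3) stop("coords must be N x 3")
  nrm <- sqrt(rowSums(coords^2))
  if (any(abs(nrm - 1) > 1e-9)) stop("coords must lie on the unit sphere")
  if (max(stats::dist(coords)) < 1e-12) stop("degenerate coords")
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(coords)
  perms <- matrix(0L, n_spins, n)
  for (s in seq_len(n_spins)) {
    # uniform random rotation via QR of a Gaussian matrix, det forced to +1
    qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
    R <- qr.Q(qr_)
    R <- R %*% diag(sign(diag(qr.R(qr_))))
    if (det(R) < 0) R[, 1] <- -R[, 1]
    rot <- coords %*% t(R)
    # nearest rotated parcel for each original parcel (dot product = cosine)
    sim <- coords %*% t(rot)
    perms[s, ] <- max.col(sim, ties.method = "first")
  }
  structure(list(permutations = perms, coords = coords),
            class = "spin_nulls")
}

#' Spin-permutation test of the correlation between two cortical maps
#'
#' Spearman correlation of `map_a` with `map_b`, compared against null
#' correlations of `map_a` with spun versions of `map_b`; two-sided add-one
#' p-value.
#'
#' @param map_a,map_b numeric vectors over the cortical parcels of `nulls`.
#' @param nulls a [build_spin_nulls()] result.
#' @return list with `rho`, `p_spin`, `null` (null correlation vector).
#' @export
spin_test <- function(map_a, map_b, nulls) {
  perms <- nulls$permutations
  n <- ncol(perms)
  if (length(map_a) != n || length(map_b) != n) {
    stop("map length (", length(map_a), "/", length(map_b),
         ") does not match spin nulls (", n, ")")
  }
  ra <- rank(map_a)
  rho <- stats::cor(ra, rank(map_b))
  null <- vapply(seq_len(nrow(perms)), function(s) {
    stats::cor(ra, rank(map_b[perms[s, ]]))
  }, numeric(1))
  p <- (1 + sum(abs(null) >= abs(rho))) / (1 + nrow(perms))
  list(rho = rho, p_spin = p, null = null)
}

#' Dominance analysis of a linear regression
#'
#' Fits ordinary least squares for all `2^p - 1` nonempty predictor subsets.
#' A predictor's total dominance is the mean, over subset sizes, of its
#' average R-squared increment when added to subsets that exclude it;
#' percent relative importance divides by the full-model R-squared, so the
#' importances sum to 100.
#'
#' @param X n x p numeric predictor matrix (p >= 1).
#' @param y numeric response.
#' @param use_adjusted if TRUE, increments use adjusted R-squared instead of
#'   raw R-squared (default FALSE, the canonical algorithm).
#' @return list with `importance_pct` (named, sums to 100),
#'   `total_dominance`, `r2_full`, `adj_r2_full`, `n_submodels`.
#' @export
dominance_analysis <- function(X, y, use_adjusted = FALSE) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (p < 1) stop("need at least one predictor")
  if (n <= p + 1) stop("need n > p + 1 observations")
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(p))
  y <- as.numeric(y)
  tss <- sum((y - mean(y))^2)
  r2 <- function(idx) {
    if (length(idx) == 0L) return(0)
    fit <- stats::lm.fit(cbind(1, X[, idx, drop = FALSE]), y)
    raw <- 1 - sum(fit$residuals^2) / tss
    if (use_adjusted) {
      1 - (1 - raw) * (n - 1) / (n - length(idx) - 1)
    } else raw
  }
  if (qr(cbind(1, X))$rank < p + 1) stop("singular design (collinear predictors)")
  # R^2 for every subset, indexed by bitmask
  nsub <- 2L^p - 1L
  r2_cache <- numeric(nsub + 1L)           # index mask + 1; mask 0 -> 0
  masks <- seq_len(nsub)
  for (m in masks) {
    r2_cache[m + 1L] <- r2(which(bitwAnd(m, bitwShiftL(1L, 0:(p - 1))) != 0))
  }
  total <- numeric(p)
  for (j in seq_len(p)) {
    bit <- bitwShiftL(1L, j - 1L)
    # subsets excluding j, grouped by size (including the empty set)
    others <- setdiff(0:nsub, masks[bitwAnd(masks, bit) != 0])
    sizes <- vapply(others, function(m) sum(bitwAnd(m, bitwShiftL(1L, 0:(p - 1))) != 0),
                    numeric(1))
    inc <- vapply(others, function(m) r2_cache[bitwOr(m, bit) + 1L] - r2_cache[m + 1L],
                  numeric(1))
    total[j] <- mean(tapply(inc, sizes, mean))
  }
  r2f_raw <- {
    fit <- stats::lm.fit(cbind(1, X), y)
    1 - sum(fit$residuals^2) / tss
  }
  r2_full <- if (use_adjusted) 1 - (1 - r2f_raw) * (n - 1) / (n - p - 1) else r2f_raw
  imp <- 100 * total / sum(total)
  names(imp) <- colnames(X)
  names(total) <- colnames(X)
  list(importance_pct = imp, total_dominance = total,
       r2_full = r2_full,
       adj_r2_full = 1 - (1 - r2f_raw) * (n - 1) / (n - p - 1),
       n_submodels = nsub)
}
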