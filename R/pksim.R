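#' Pharmacokinetic model parameters
#'
#' Linear mammillary compartment model with zero-order intravenous infusion
#' and a first-order effect compartment (`dCe/dt = ke0 (Cp - Ce)`). The
#' defaults are a documented synthetic two-compartment parameter set with
#' kinetics on the timescale of a short-acting intravenous psychedelic
#' (distribution + elimination half-lives of a few minutes); to reproduce a
#' published population model, supply its estimates here or import its
#' concentration curve directly via [concentration_series()].
#'
#' @param n_compartments 1-3 mammillary compartments.
#' @param volumes litres per compartment (central first).
#' @param k_elim elimination rate constant from the central compartment
#'   (1/min).
#' @param k_distribute length-2(n-1) vector of inter-compartment rates
#'   c(k1j, kj1) per peripheral compartment (1/min).
#' @param ke0 effect-compartment equilibration rate (1/min).
#' @param dose_mg infused dose.
#' @param infusion_seconds infusion duration (default 30).
#' @param flush optional list(dose_mg=, start_seconds=, duration_seconds=)
#'   for a saline-flush second zero-order input.
#' @export
pk_params <- function(n_compartments = 2,
                      volumes = c(15, 40),
                      k_elim = 0.2,
                      k_distribute = c(0.35, 0.12),
                      ke0 = 0.6,
                      dose_mg = 20,
                      infusion_seconds = 30,
                      flush = NULL) {
  if (n_compartments < 1 || n_compartments > 3) stop("1-3 compartments")
  if (length(volumes) != n_compartments) stop("one volume per compartment")
  if (length(k_distribute) != 2 * (n_compartments - 1)) {
    stop("need c(k1j, kj1) per peripheral compartment")
  }
  if (any(c(volumes, k_elim, ke0, dose_mg, infusion_seconds) <= 0) ||
      any(k_distribute <= 0)) {
    stop("all rates, volumes, dose and infusion duration must be positive")
  }
  structure(list(n_compartments = n_compartments, volumes = volumes,
                 k_elim = k_elim, k_distribute = k_distribute, ke0 = ke0,
                 dose_mg = dose_mg, infusion_seconds = infusion_seconds,
                 flush = flush),
            class = "pk_params")
}

#' Wrap an externally simulated concentration curve
#'
#' @param times seconds.
#' @param plasma,effect concentration vectors (ng/mL or any common unit).
#' @export
concentration_series <- function(times, plasma, effect = plasma) {
  if (length(times) != length(plasma) || length(times) != length(effect)) {
    stop("length mismatch")
  }
  if (any(plasma < -1e-12) || any(effect < -1e-12)) {
    stop("concentrations must be nonnegative")
  }
  structure(list(times = as.numeric(times),
                 plasma = pmax(plasma, 0), effect = pmax(effect, 0)),
            class = "concentration_series")
}

#' Simulate plasma and effect-compartment concentrations
#'
#' Solves the compartment ODEs analytically: on each interval with constant
#' input rate the augmented linear system is propagated by a single matrix
#' exponential (no integration error). The state carries compartment amounts
#' (mg) and the effect-compartment concentration; plasma concentration is
#' the central amount over the central volume. Output is scaled to
#' micrograms per litre (= ng/mL).
#'
#' @param p a [pk_params()].
#' @param grid_seconds evaluation times (seconds from infusion start);
#'   negative times return zero concentration.
#' @return [concentration_series()]
#' @export
simulate_concentration <- function(p, grid_seconds) {
  nc <- p$n_compartments
  nst <- nc + 1L                       # amounts + effect concentration
  # rate matrix in 1/min
  K <- matrix(0, nst, nst)
  K[1, 1] <- -p$k_elim
  if (nc > 1) {
    for (j in seq_len(nc - 1)) {
      k1j <- p$k_distribute[2 * j - 1]
      kj1 <- p$k_distribute[2 * j]
      K[1, 1] <- K[1, 1] - k1j
      K[j + 1, 1] <- k1j
      K[1, j + 1] <- kj1
      K[j + 1, j + 1] <- -kj1
    }
  }
  K[nst, 1] <- p$ke0 / p$volumes[1]    # Ce' = ke0 (A1/V1 - Ce)
  K[nst, nst] <- -p$ke0

  inputs <- list(list(rate = p$dose_mg / (p$infusion_seconds / 60),
                      start = 0, end = p$infusion_seconds))
  if (!is.null(p$flush) && p$flush$dose_mg > 0) {
    inputs[[2]] <- list(
      rate = p$flush$dose_mg / (p$flush$duration_seconds / 60),
      start = p$flush$start_seconds,
      end = p$flush$start_seconds + p$flush$duration_seconds)
  }
  breaks <- sort(unique(c(0, unlist(lapply(inputs, function(i) c(i$start, i$end))),
                          grid_seconds[grid_seconds >= 0])))
  rate_at <- function(t) {
    r <- 0
    for (i in inputs) if (t >= i$start && t < i$end) r <- r + i$rate
    r
  }
  x <- numeric(nst)
  sol <- matrix(0, length(breaks), nst)
  for (i in seq_along(breaks)[-1]) {
    h <- (breaks[i] - breaks[i - 1]) / 60   # minutes
    r <- rate_at(breaks[i - 1])
    # augmented propagation handles constant input without inverting K
    Aug <- rbind(cbind(K, c(r, rep(0, nst - 1))), rep(0, nst + 1))
    E <- ce_expm(Aug * h)
    x <- as.numeric(E[seq_len(nst), ] %*% c(x, 1))
    sol[i, ] <- x
  }
  idx <- match(pmax(grid_seconds, 0), breaks)
  plasma <- ifelse(grid_seconds < 0, 0, sol[idx, 1] / p$volumes[1]) * 1000
  effect <- ifelse(grid_seconds < 0, 0, sol[idx, nst]) * 1000
  concentration_series(grid_seconds, plasma, effect)
}

#' Build a time-varying control schedule from drug concentration
#'
#' Pre-injection transitions keep the uniform strategy (all weights 1).
#' Post-injection, with the normalized concentration `c(t)` (peak 1) and
#' normalized receptor density `r` (mean 1):
#' \describe{
#'   \item{additive}{`v_i(t) = 1 + alpha (c(t) + r_i)` — extra control is
#'     injected as the sum of a global concentration term and a static
#'     receptor-weighted term.}
#'   \item{multiplicative}{`v_i(t) = 1 + alpha c(t) r_i` — receptor density
#'     gates the concentration effect per region.}
#' }
#'
#' @param conc a [concentration_series()] with times in seconds relative to
#'   the injection.
#' @param rmap a [receptor_map()] (or plain density vector).
#' @param alpha nonnegative scaling of the added control.
#' @param mode "additive" or "multiplicative".
#' @param source use "effect" (default) or "plasma" concentrations.
#' @param uniform_density replace the density vector by its mean, spread
#'   uniformly (alternative-model comparison).
#' @param n_transitions,tr_seconds,injection_volume transition-grid layout.
#' @return a [control_schedule()]
#' @export
build_schedule <- function(conc, rmap, alpha,
                           mode = c("additive", "multiplicative"),
                           source = c("effect", "plasma"),
                           uniform_density = FALSE,
                           n_transitions, tr_seconds = 2,
                           injection_volume) {
  mode <- match.arg(mode)
  source <- match.arg(source)
  if (alpha < 0) stop("alpha must be nonnegative")
  dens <- if (inherits(rmap, "receptor_map")) rmap$density else as.numeric(rmap)
  n <- length(dens)
  if (uniform_density) dens <- rep(mean(dens), n)
  if (mean(dens) <= 0) stop("density must have positive mean")
  r <- dens / mean(dens)
  cs <- if (source == "effect") conc$effect else conc$plasma
  cnorm <- if (max(cs) > 0) cs / max(cs) else cs
  # transition k joins volumes k, k+1; mid-time relative to injection
  mid <- (seq_len(n_transitions) - 0.5) * tr_seconds -
    injection_volume * tr_seconds
  ck <- stats::approx(conc$times, cnorm, xout = mid, rule = 2)$y
  v <- matrix(1, n, n_transitions)
  post <- which(seq_len(n_transitions) > injection_volume)
  for (k in post) {
    v[, k] <- if (mode == "additive") 1 + alpha * (ck[k] + r)
              else 1 + alpha * ck[k] * r
  }
  if (any(v < 1)) stop("schedule entries below 1 (should be impossible)")
  control_schedule(v)
}

#' Predict drug-condition energy from placebo data
#'
#' Runs [energy_timeseries()] on each subject's placebo state sequence under
#' a (typically time-varying) control schedule and returns per-subject
#' profiles plus the group mean.
#'
#' @param placebo_list list of placebo [state_series()] (one per subject).
#' @param A_s stabilized dynamics operator.
#' @param schedule a [control_schedule()].
#' @param cfg a [control_config()].
#' @param regional compute regional energies too (default FALSE: the
#'   simulation is assessed on the global series).
#' @return list with `subject_profiles` and `group_mean` (global series).
#' @export
simulate_drug_energy <- function(placebo_list, A_s, schedule,
                                 cfg = control_config(), regional = FALSE) {
  profs <- lapply(placebo_list, function(s) {
    energy_timeseries(s, A_s, schedule, cfg, regional = regional)
  })
  g <- rowMeans(vapply(profs, `[[`, numeric(length(profs[[1]]$global)),
                       "global"))
  list(subject_profiles = profs, group_mean = g)
}

#' Grid search for the control-scaling parameter alpha
#'
#' For each candidate alpha the drug-condition global energy series is
#' simulated from placebo data and compared with the empirical drug series
#' by Euclidean distance; the minimizer is returned.
#'
#' @param placebo_list list of placebo [state_series()].
#' @param empirical_drug_global empirical group-mean global energy series.
#' @param A_s stabilized dynamics operator.
#' @param conc a [concentration_series()].
#' @param rmap a [receptor_map()] or density vector.
#' @param grid candidate alphas (default c(1, 10, 20, ..., 70)).
#' @param mode,source,uniform_density passed to [build_schedule()].
#' @param cfg a [control_config()].
#' @param post_only compare post-injection transitions only (default FALSE:
#'   full series).
#' @return list with `alpha` (argmin), `distances` (named vector), and
#'   `simulated` (group-mean series at the best alpha).
#' @export
fit_alpha_grid <- function(placebo_list, empirical_drug_global, A_s,
                           conc, rmap,
                           grid = c(1, 10, 20, 30, 40, 50, 60, 70),
                           mode = "additive", source = "effect",
                           uniform_density = FALSE,
                           cfg = control_config(), post_only = FALSE) {
  if (length(grid) == 0) stop("empty alpha grid")
  M <- length(empirical_drug_global)
  inj <- placebo_list[[1]]$injection_volume
  tr <- placebo_list[[1]]$tr_seconds
  idx <- if (post_only) injection_split(M, inj)$post else seq_len(M)
  dist_v <- numeric(length(grid))
  best <- NULL
  for (i in seq_along(grid)) {
    sched <- build_schedule(conc, rmap, grid[i], mode = mode, source = source,
                            uniform_density = uniform_density,
                            n_transitions = M, tr_seconds = tr,
                            injection_volume = inj)
    sim <- simulate_drug_energy(placebo_list, A_s, sched, cfg,
                                regional = FALSE)
    dist_v[i] <- sqrt(sum((sim$group_mean[idx] -
                             empirical_drug_global[idx])^2))
    if (i == 1 || dist_v[i] < min(dist_v[seq_len(i - 1)])) {
      best <- sim$group_mean
    }
  }
  names(dist_v) <- grid
  list(alpha = grid[which.min(dist_v)], distances = dist_v, simulated = best)
}

#' Compare alternative simulation models
#'
#' Evaluates the best-alpha distance for combinations of concentration
#' source (effect vs plasma compartment) and spatial weighting (receptor map
#' vs uniform).
#'
#' @inheritParams fit_alpha_grid
#' @param variants subset of c("effect+receptor", "plasma+receptor",
#'   "effect+uniform").
#' @return data.frame with variant, best alpha, and distance.
#' @export
compare_models <- function(placebo_list, empirical_drug_global, A_s,
                           conc, rmap,
                           variants = c("effect+receptor", "plasma+receptor",
                                        "effect+uniform"),
                           grid = c(1, 10, 20, 30, 40, 50, 60, 70),
                           mode = "additive", cfg = control_config()) {
  known <- c("effect+receptor", "plasma+receptor", "effect+uniform")
  if (!all(variants %in% known)) {
    stop("unknown variant: ", paste(setdiff(variants, known), collapse = ", "))
  }
  res <- NULL
  for (v in variants) {
    src <- if (startsWith(v, "plasma")) "plasma" else "effect"
    uni <- endsWith(v, "uniform")
    fit <- fit_alpha_grid(placebo_list, empirical_drug_global, A_s, conc,
                          rmap, grid = grid, mode = mode, source = src,
                          uniform_density = uni, cfg = cfg)
    res <- rbind(res, data.frame(variant = v, alpha = fit$alpha,
                                 distance = min(fit$distances)))
  }
  res
}
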