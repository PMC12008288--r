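#' Configuration for the synthetic study generator
#'
#' Defaults mirror the geometry of a two-condition pharmaco-fMRI/EEG study:
#' 116 regions (100 cortical + 16 subcortical), 14 subjects, 840 volumes at
#' TR = 2 s (28 min) with the drug injected at the end of the 8th minute
#' (240 pre-injection volumes).
#'
#' @param n_regions total region count.
#' @param n_cortical cortical region count (spin tests; receptor maps).
#' @param n_subjects paired subjects.
#' @param n_volumes volumes per scan.
#' @param tr repetition time (s).
#' @param injection_volume number of pre-injection volumes.
#' @param beta drug effect size: maximum fractional BOLD amplitude damping
#'   at the concentration peak (0 <= beta < 1).
#' @param gamma receptor coupling in \[0, 1\]: 1 = damping fully weighted by
#'   the receptor map, 0 = spatially uniform damping.
#' @param noise_sd innovation SD of the BOLD autoregressive process.
#' @param rho_ar temporal autocorrelation of the BOLD process.
#' @param seed master seed; every generator derives its stream from it.
#' @export
synth_config <- function(n_regions = 116, n_cortical = 100,
                         n_subjects = 14, n_volumes = 840, tr = 2,
                         injection_volume = 240,
                         beta = 0.35, gamma = 0.8,
                         noise_sd = 1, rho_ar = 0.6, seed = 1) {
  stopifnot(n_regions >= 8, n_cortical >= 10, n_cortical < n_regions,
            n_subjects >= 1, n_volumes >= 2,
            injection_volume >= 0, injection_volume < n_volumes,
            beta >= 0, beta < 1, gamma >= 0, gamma <= 1, noise_sd > 0)
  structure(as.list(environment()), class = "synth_config")
}

yeo7_names <- c("Vis", "SomMot", "DorsAttn", "SalVentAttn",
                "Limbic", "Cont", "Default")

# rise-and-decay concentration-like gate, peak 1, time in minutes post event
effect_gate <- function(t_min, rise = 0.8, decay = 6) {
  g <- ifelse(t_min <= 0, 0, exp(-t_min / decay) - exp(-t_min / rise))
  tpk <- rise * decay / (decay - rise) * log(decay / rise)
  g / (exp(-tpk / decay) - exp(-tpk / rise))
}

#' Generate a modular weighted connectome
#'
#' Eight modules (seven cortical networks + subcortex) with
#' distance-dependent weight decay on random 3D module-clustered
#' coordinates; weights are symmetric, nonnegative, zero-diagonal.
#'
#' @param cfg a [synth_config()].
#' @return `structural_connectome` with network assignments.
#' @export
gen_connectome <- function(cfg) {
  set.seed(cfg$seed + 101L)
  n <- cfg$n_regions
  ncx <- cfg$n_cortical
  if (n < 8) stop("need at least as many regions as modules")
  nets <- c(rep(yeo7_names, length.out = ncx)[order(rep(seq_len(7),
             length.out = ncx))],
            rep("Subcortex", n - ncx))
  # module centers on a sphere of radius 3; members jittered around them
  centers <- matrix(stats::rnorm(8 * 3), 8, 3)
  centers <- 3 * centers / sqrt(rowSums(centers^2))
  mod_idx <- match(nets, c(yeo7_names, "Subcortex"))
  xyz <- centers[mod_idx, ] + matrix(stats::rnorm(n * 3, sd = 0.8), n, 3)
  d <- as.matrix(stats::dist(xyz))
  same <- outer(mod_idx, mod_idx, "==")
  w <- exp(-d / 2) * (1 + 2 * same) *
    matrix(stats::rgamma(n * n, shape = 3, rate = 3), n, n)
  w <- (w + t(w)) / 2
  diag(w) <- 0
  structural_connectome(w, region_labels = sprintf("%s_%03d", nets, seq_len(n)),
                        network_assignment = nets)
}

#' Generate a spatially autocorrelated receptor map
#'
#' Cortical parcel centroids are placed (or reused) on the unit sphere and a
#' Gaussian-process sample with squared-exponential covariance over chordal
#' distance is exponentiated into a positive density; subcortical densities
#' are independent lognormals.
#'
#' @param cfg a [synth_config()].
#' @param smoothness GP length-scale (chordal distance units; ~0 gives a
#'   near-iid map, >= 0.5 strongly autocorrelated).
#' @param coords optional precomputed N_cortical x 3 unit-sphere centroids
#'   (share across maps of one study).
#' @param name receptor name string.
#' @param seed_offset stream offset so multiple maps differ.
#' @return `receptor_map` with `$coords` filled.
#' @export
gen_receptor_map <- function(cfg, smoothness = 0.6, coords = NULL,
                             name = "5-HT2a", seed_offset = 0L) {
  if (smoothness < 0) stop("invalid smoothness")
  set.seed(cfg$seed + 211L + seed_offset)
  ncx <- cfg$n_cortical
  if (is.null(coords)) {
    coords <- matrix(stats::rnorm(ncx * 3), ncx, 3)
    coords <- coords / sqrt(rowSums(coords^2))
  }
  if (smoothness < 1e-6) {
    z <- stats::rnorm(ncx)
  } else {
    d2 <- as.matrix(stats::dist(coords))^2
    Kc <- exp(-d2 / (2 * smoothness^2)) + diag(1e-8, ncx)
    z <- as.numeric(t(chol(Kc)) %*% stats::rnorm(ncx))
  }
  dens_cx <- exp(0.6 * z)
  dens_sc <- exp(stats::rnorm(cfg$n_regions - ncx, sd = 0.6))
  receptor_map(c(dens_cx, dens_sc), receptor_name = name,
               cortical_mask = c(rep(TRUE, ncx),
                                 rep(FALSE, cfg$n_regions - ncx)),
               coords = coords)
}

#' Generate paired BOLD state sequences for both conditions
#'
#' Both conditions evolve as a stationary first-order autoregressive
#' process coupled through the connectome,
#' `x_{t+1} = rho_ar M x_t + eps_t`, with `M` the connectome scaled to unit
#' spectral radius. The drug condition additionally applies a
#' post-injection multiplicative amplitude damping
#' `s_i(t) = 1 - beta_s g(t) (gamma r_i + (1 - gamma))`, where `g(t)` is a
#' rise-and-decay concentration-like gate, `r_i` the receptor density
#' scaled to max 1, and `beta_s` a per-subject lognormal perturbation of
#' `beta`. Conditions use independent innovation streams; everything is
#' deterministic given `cfg$seed`.
#'
#' @param cfg a [synth_config()].
#' @param connectome a `structural_connectome` (from [gen_connectome()]).
#' @param rmap a `receptor_map` weighting the drug effect.
#' @return list with `drug` and `placebo`: lists of [state_series()], one
#'   per subject; plus `gate` (per-volume damping gate) and `beta_subject`.
#' @export
gen_bold <- function(cfg, connectome, rmap) {
  n <- cfg$n_regions; V <- cfg$n_volumes
  w <- connectome$weights
  M <- w / eigen(w, symmetric = TRUE, only.values = TRUE)$values[1]
  r01 <- rmap$density / max(rmap$density)
  weight <- cfg$gamma * r01 + (1 - cfg$gamma)
  t_min <- ((seq_len(V) - cfg$injection_volume) * cfg$tr) / 60
  gate <- effect_gate(t_min)
  set.seed(cfg$seed + 307L)
  beta_s <- cfg$beta * exp(stats::rnorm(cfg$n_subjects, sd = 0.15))
  if (any(beta_s * max(gate) * max(weight) >= 1)) {
    stop("drug effect would flip state sign: reduce beta")
  }
  ar_series <- function() {
    X <- matrix(0, n, V)
    # burn-in to stationarity
    x <- stats::rnorm(n, sd = cfg$noise_sd)
    for (t in 1:50) x <- cfg$rho_ar * (M %*% x) + stats::rnorm(n, sd = cfg$noise_sd)
    X[, 1] <- x
    for (t in 2:V) {
      X[, t] <- cfg$rho_ar * (M %*% X[, t - 1]) +
        stats::rnorm(n, sd = cfg$noise_sd)
    }
    X
  }
  placebo <- vector("list", cfg$n_subjects)
  drug <- vector("list", cfg$n_subjects)
  for (s in seq_len(cfg$n_subjects)) {
    Xp <- ar_series()
    placebo[[s]] <- state_series(Xp, cfg$tr, cfg$injection_volume,
                                 sprintf("s%02d", s), "placebo")
    Xd <- ar_series()
    scale <- 1 - beta_s[s] * outer(weight, gate)   # n x V
    drug[[s]] <- state_series(Xd * scale, cfg$tr, cfg$injection_volume,
                              sprintf("s%02d", s), "drug")
  }
  list(drug = drug, placebo = placebo, gate = gate, beta_subject = beta_s)
}

#' Generate coupled reference series (diversity and intensity)
#'
#' Signal diversity is constructed inversely coupled to the global energy
#' series (`a - b * standardized(energy) + noise`, `b > 0`); subjective
#' intensity is a discretized 0-10 rise-and-decay curve peaking shortly
#' after injection, zero before it.
#'
#' @param cfg a [synth_config()].
#' @param energy_global global energy series on the transition grid.
#' @param diversity_noise_sd SD of the additive noise on diversity.
#' @param seed_offset stream offset (distinct per condition).
#' @return list with `diversity` (transition grid) and `intensity`
#'   (per-minute, length = scan minutes).
#' @export
gen_reference_series <- function(cfg, energy_global,
                                 diversity_noise_sd = 0.5,
                                 seed_offset = 0L) {
  set.seed(cfg$seed + 401L + seed_offset)
  zs <- (energy_global - mean(energy_global)) / stats::sd(energy_global)
  diversity <- 40 - 4 * zs + stats::rnorm(length(zs), sd = diversity_noise_sd)
  minutes <- floor(cfg$n_volumes * cfg$tr / 60)
  inj_min <- cfg$injection_volume * cfg$tr / 60
  m <- seq_len(minutes)
  intensity <- pmin(10, pmax(0, round(10 * 0.92 *
    effect_gate(m - inj_min, rise = 0.5, decay = 7))))
  list(diversity = diversity, intensity = intensity)
}

#' Generate a complete synthetic study
#'
#' Orchestrates the generators into one deterministic dataset: connectome,
#' five receptor maps sharing one set of spherical centroids (the first map
#' drives the drug effect), paired BOLD series, and reference series derived
#' from the drug condition's group-mean global energy.
#'
#' @param cfg a [synth_config()].
#' @param cfg_control a [control_config()] for the internal energy pass used
#'   to couple the reference series.
#' @return list with `connectome`, `A_s`, `receptor_maps` (named list),
#'   `coords`, `bold` (drug/placebo lists), `drug_profiles`,
#'   `placebo_profiles` (per-subject energy profiles), `diversity`,
#'   `intensity`, `cfg`.
#' @export
synth_study <- function(cfg = synth_config(),
                        cfg_control = control_config()) {
  sc <- gen_connectome(cfg)
  A_s <- stabilize(sc)
  rnames <- c("5-HT2a", "5-HT1a", "5-HT1b", "5-HT4", "5-HTT")
  maps <- vector("list", 5)
  maps[[1]] <- gen_receptor_map(cfg, name = rnames[1])
  for (i in 2:5) {
    maps[[i]] <- gen_receptor_map(cfg, coords = maps[[1]]$coords,
                                  name = rnames[i],
                                  seed_offset = 13L * i)
  }
  names(maps) <- rnames
  bold <- gen_bold(cfg, sc, maps[[1]])
  dprof <- lapply(bold$drug, energy_timeseries, A_s = A_s, cfg = cfg_control,
                  network_assignment = sc$network_assignment)
  pprof <- lapply(bold$placebo, energy_timeseries, A_s = A_s,
                  cfg = cfg_control,
                  network_assignment = sc$network_assignment)
  gmean_drug <- rowMeans(vapply(dprof, `[[`,
                                numeric(length(dprof[[1]]$global)), "global"))
  gmean_pcb <- rowMeans(vapply(pprof, `[[`,
                               numeric(length(pprof[[1]]$global)), "global"))
  refs_d <- gen_reference_series(cfg, gmean_drug, seed_offset = 0L)
  refs_p <- gen_reference_series(cfg, gmean_pcb, seed_offset = 1L)
  list(connectome = sc, A_s = A_s, receptor_maps = maps,
       coords = maps[[1]]$coords, bold = bold,
       drug_profiles = dprof, placebo_profiles = pprof,
       diversity_drug = refs_d$diversity,
       diversity_placebo = refs_p$diversity,
       intensity = refs_d$intensity,
       cfg = cfg)
}
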