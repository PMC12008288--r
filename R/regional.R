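#' Regional receptor/transporter density map
#'
#' @param density nonnegative numeric vector, one value per region in the
#'   full atlas layout (cortex first, then subcortex by convention).
#' @param receptor_name e.g. "5-HT2a", "5-HT1a", "5-HT1b", "5-HT4", "5-HTT".
#' @param cortical_mask logical vector marking the cortical regions (spin
#'   tests operate on these only; subcortex cannot be spin permuted).
#' @param coords optional N_cortex x 3 unit-sphere centroids for spin nulls.
#' @export
receptor_map <- function(density, receptor_name = "5-HT2a",
                         cortical_mask = NULL, coords = NULL) {
  density <- as.numeric(density)
  if (any(density < 0)) stop("densities must be nonnegative")
  if (is.null(cortical_mask)) cortical_mask <- rep(TRUE, length(density))
  if (length(cortical_mask) != length(density)) stop("mask length mismatch")
  structure(list(density = density, receptor_name = receptor_name,
                 cortical_mask = as.logical(cortical_mask), coords = coords),
            class = "receptor_map")
}

#' @export
print.receptor_map <- function(x, ...) {
  cat("receptor_map:", x$receptor_name, "|", length(x$density), "regions (",
      sum(x$cortical_mask), "cortical )\n")
  invisible(x)
}

# transitions strictly before / strictly after the injection. Transition k
# joins volumes k and k+1; the transition crossing the injection (k =
# injection_volume) belongs to neither side.
injection_split <- function(n_transitions, injection_volume) {
  pre <- seq_len(max(0L, injection_volume - 1L))
  post <- if (injection_volume + 1L <= n_transitions) {
    seq.int(injection_volume + 1L, n_transitions)
  } else integer(0)
  list(pre = pre, post = post)
}

#' Post- vs pre-injection change in regional control energy
#'
#' Per region: (mean energy over the first `window_minutes` post-injection
#' minus mean over the `window_minutes` pre-injection) divided by the
#' pre-injection mean. Equal transition counts are used on both sides (the
#' window is truncated to what is available on the shorter side). Set
#' `relative = FALSE` for the absolute difference.
#'
#' @param profile an `energy_profile` with regional energies.
#' @param injection_volume number of pre-injection volumes; default taken
#'   from the profile.
#' @param window_minutes window length (default 8).
#' @param tr_seconds repetition time; default from the profile.
#' @param relative divide by the pre-injection mean (default TRUE).
#' @return per-region numeric vector.
#' @export
post_pre_change <- function(profile, injection_volume = NULL,
                            window_minutes = 8, tr_seconds = NULL,
                            relative = TRUE) {
  inj <- if (is.null(injection_volume)) profile$injection_volume
         else injection_volume
  tr <- if (is.null(tr_seconds)) profile$tr_seconds else tr_seconds
  reg <- profile$regional
  if (is.null(reg)) stop("profile lacks regional energies")
  M <- ncol(reg)
  sp <- injection_split(M, inj)
  w <- as.integer(round(window_minutes * 60 / tr))
  w <- min(w, length(sp$pre), length(sp$post))
  if (w < 1) stop("not enough data on both sides of the injection")
  pre_idx <- utils::tail(sp$pre, w)
  post_idx <- utils::head(sp$post, w)
  pre_m <- rowMeans(reg[, pre_idx, drop = FALSE])
  post_m <- rowMeans(reg[, post_idx, drop = FALSE])
  if (!relative) return(post_m - pre_m)
  if (any(pre_m == 0)) stop("zero pre-injection mean energy in region(s) ",
                            paste(which(pre_m == 0), collapse = ", "))
  (post_m - pre_m) / pre_m
}

#' Correlate each region's energy series with a reference series
#'
#' Spearman rho per region between the (optionally one-minute-windowed)
#' energy time-series and a reference series such as HRF-aligned signal
#' diversity or per-minute subjective intensity ratings. Series are trimmed
#' to their common length after windowing.
#'
#' @param profile an `energy_profile` (typically a group mean).
#' @param reference numeric reference series.
#' @param windowed average energies over 60 s windows first (for per-minute
#'   references).
#' @return per-region vector of Spearman rho.
#' @export
regional_coupling <- function(profile, reference, windowed = FALSE) {
  reg <- profile$regional
  if (is.null(reg)) stop("profile lacks regional energies")
  if (windowed) {
    reg <- t(apply(reg, 1, windowed_mean, window_seconds = 60,
                   tr_seconds = profile$tr_seconds))
  }
  len <- min(ncol(reg), length(reference))
  if (len < 3) stop("length mismatch after alignment")
  reg <- reg[, seq_len(len), drop = FALSE]
  ref_r <- rank(reference[seq_len(len)])
  apply(reg, 1, function(e) stats::cor(rank(e), ref_r))
}

#' Difference of two group-mean series
#'
#' Elementwise drug minus placebo; the delta series underlying the
#' energy-diversity and energy-intensity coupling analyses.
#'
#' @param group_mean_drug,group_mean_placebo equal-length numeric vectors.
#' @export
delta_series <- function(group_mean_drug, group_mean_placebo) {
  if (length(group_mean_drug) != length(group_mean_placebo)) {
    stop("length mismatch")
  }
  group_mean_drug - group_mean_placebo
}

#' Receptor-map association of a regional metric
#'
#' Cortical-only Spearman correlation with spin-permutation p-value
#' (delegating to [spin_test()]); optionally also the subcortex-inclusive
#' correlation, reported without a p-value.
#'
#' @param metric per-region numeric vector (full atlas layout).
#' @param rmap a [receptor_map()].
#' @param nulls a [build_spin_nulls()] result over the cortical parcels.
#' @param include_subcortex also report the all-region rho.
#' @return list with `rho`, `p_spin`, and optionally `rho_all`.
#' @export
receptor_association <- function(metric, rmap, nulls,
                                 include_subcortex = FALSE) {
  if (length(metric) != length(rmap$density)) stop("mask mismatch")
  cm <- rmap$cortical_mask
  st <- spin_test(metric[cm], rmap$density[cm], nulls)
  out <- list(rho = st$rho, p_spin = st$p_spin)
  if (include_subcortex) {
    out$rho_all <- stats::cor(rank(metric), rank(rmap$density))
  }
  out
}

#' Per-network t-statistic summaries over post-injection halves
#'
#' Paired t statistics per transition between conditions, averaged over the
#' first and second halves of the post-injection period, per network.
#'
#' @param a,b lists of `energy_profile`s (one per subject, same order) for
#'   the two conditions; network rows must be present.
#' @param injection_volume default from the first profile.
#' @return data.frame with columns network, half, mean_t.
#' @export
halfperiod_tstats <- function(a, b, injection_volume = NULL) {
  if (length(a) != length(b) || length(a) < 2) stop("need paired subject lists")
  nets <- rownames(a[[1]]$network)
  if (is.null(nets)) stop("profiles lack network energies")
  inj <- if (is.null(injection_volume)) a[[1]]$injection_volume
         else injection_volume
  M <- length(a[[1]]$global)
  sp <- injection_split(M, inj)
  post <- sp$post
  if (length(post) < 2) stop("empty post-injection half")
  h1 <- post[seq_len(length(post) %/% 2)]
  h2 <- post[(length(post) %/% 2 + 1):length(post)]
  ns <- length(a)
  res <- NULL
  for (nm in nets) {
    da <- t(vapply(a, function(p) p$network[nm, ], numeric(M)))
    db <- t(vapply(b, function(p) p$network[nm, ], numeric(M)))
    d <- da - db
    m <- colMeans(d)
    s <- sqrt((colSums(d^2) - ns * m^2) / (ns - 1))
    tv <- m / (s / sqrt(ns))
    res <- rbind(res,
                 data.frame(network = nm, half = c("first", "second"),
                            mean_t = c(mean(tv[h1]), mean(tv[h2]))))
  }
  res
}

#' Group-mean energy profile
#'
#' Averages global (and where present regional/network) energies across a
#' list of per-subject profiles.
#'
#' @param profiles list of `energy_profile`s with matching dimensions.
#' @export
group_mean_profile <- function(profiles) {
  g <- rowMeans(vapply(profiles, `[[`, numeric(length(profiles[[1]]$global)),
                       "global"))
  out <- profiles[[1]]
  out$global <- g
  if (!is.null(out$regional)) {
    acc <- Reduce(`+`, lapply(profiles, `[[`, "regional"))
    out$regional <- acc / length(profiles)
  }
  if (!is.null(out$network)) {
    acc <- Reduce(`+`, lapply(profiles, `[[`, "network"))
    out$network <- acc / length(profiles)
  }
  out$subject_id <- "group-mean"
  out
}
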