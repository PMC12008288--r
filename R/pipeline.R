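#' Write a numeric matrix/vector as TSV with a JSON sidecar
#'
#' @param x matrix or vector.
#' @param path output TSV path; the sidecar is `<path>.json`.
#' @param meta named list recorded in the sidecar.
#' @export
write_tsv_sidecar <- function(x, path, meta = list()) {
  m <- as.matrix(x)
  if (is.null(rownames(m))) {
    utils::write.table(m, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
  } else {
    utils::write.table(m, path, sep = "\t", quote = FALSE,
                       row.names = TRUE, col.names = NA)
  }
  meta$written <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  meta$dim <- dim(m)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(path)
}

#' Read a state series from TSV + JSON sidecar
#'
#' @param path TSV with regions as rows, volumes as columns; sidecar
#'   `<path>.json` must carry tr_seconds, injection_volume, subject_id,
#'   condition.
#' @export
read_state_series <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  m <- as.matrix(utils::read.table(path, sep = "\t", header = TRUE,
                                   row.names = 1, check.names = FALSE))
  state_series(m, tr_seconds = meta$tr_seconds,
               injection_volume = meta$injection_volume,
               subject_id = meta$subject_id, condition = meta$condition)
}

#' Run the full analysis pipeline on a synthetic or loaded study
#'
#' Executes the stages in order — energy computation, global statistics
#' (cluster test + delta-series correlations), network summaries, regional
#' metrics, receptor association with spin nulls, dominance analysis, and
#' the pharmacokinetic simulation with alpha grid search — writing TSV/JSON
#' results and a manifest to `out_dir`. Any stage can be switched off.
#'
#' @param study a [synth_study()] result (or an equivalently shaped list of
#'   loaded data).
#' @param out_dir output directory (created if missing).
#' @param n_perm permutations for the cluster test and Spearman tests.
#' @param n_spins spin permutations.
#' @param alpha_grid candidate alphas for the simulation stage.
#' @param pk a [pk_params()] for the simulation stage.
#' @param seed master seed for all stochastic stages.
#' @param stages character subset of c("energy", "global", "network",
#'   "regional", "dominance", "pksim").
#' @param state_norm state normalization variant recorded and applied.
#' @return invisibly, a list of all stage results.
#' @export
run_pipeline <- function(study, out_dir,
                         n_perm = 1000, n_spins = 1000,
                         alpha_grid = c(1, 10, 20, 30, 40, 50, 60, 70),
                         pk = pk_params(), seed = 1,
                         stages = c("energy", "global", "network",
                                    "regional", "dominance", "pksim"),
                         state_norm = "none") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- list()
  t0 <- Sys.time()
  log_stage <- function(name) {
    message(sprintf("[%s] stage %s (%.1f s elapsed)",
                    format(Sys.time(), "%H:%M:%S"), name,
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  }
  need <- function(field, stage) {
    if (is.null(study[[field]])) {
      stop("stage '", stage, "': missing input '", field, "'")
    }
    study[[field]]
  }
  cfg <- study$cfg
  M <- length(study$drug_profiles[[1]]$global)
  inj <- study$drug_profiles[[1]]$injection_volume
  ga <- function(profiles) {
    t(vapply(profiles, `[[`, numeric(M), "global"))
  }

  if ("energy" %in% stages) {
    log_stage("energy")
    gmd <- colMeans(ga(need("drug_profiles", "energy")))
    gmp <- colMeans(ga(need("placebo_profiles", "energy")))
    res$energy <- list(group_mean_drug = gmd, group_mean_placebo = gmp)
    write_tsv_sidecar(rbind(drug = gmd, placebo = gmp),
                      file.path(out_dir, "global_energy_group_mean.tsv"),
                      list(state_norm = state_norm, seed = seed))
  }

  if ("global" %in% stages) {
    log_stage("global")
    if (is.null(res$energy)) stop("stage 'global': requires stage 'energy'")
    ct <- paired_cluster_test(ga(study$drug_profiles),
                              ga(study$placebo_profiles),
                              n_perm = n_perm, seed = seed)
    sp <- injection_split(M, inj)
    frac_sig <- mean(ct$significant_mask[sp$post])
    dE <- delta_series(res$energy$group_mean_drug,
                       res$energy$group_mean_placebo)
    dLZ <- delta_series(study$diversity_drug, study$diversity_placebo)
    cor_div <- perm_spearman(dE, dLZ, n_perm = n_perm, seed = seed + 1)
    dE_min <- windowed_mean(dE, 60, study$drug_profiles[[1]]$tr_seconds)
    len <- min(length(dE_min), length(study$intensity))
    cor_int <- perm_spearman(dE_min[seq_len(len)],
                             study$intensity[seq_len(len)],
                             n_perm = n_perm, seed = seed + 2)
    res$global <- list(cluster = ct, frac_post_significant = frac_sig,
                       delta_energy_diversity = cor_div,
                       delta_energy_intensity = cor_int)
    write_tsv_sidecar(ct$clusters, file.path(out_dir, "clusters.tsv"),
                      list(n_perm = n_perm, seed = seed,
                           frac_post_significant = frac_sig))
  }

  if ("network" %in% stages) {
    log_stage("network")
    res$network <- halfperiod_tstats(study$drug_profiles,
                                     study$placebo_profiles)
    write_tsv_sidecar(res$network,
                      file.path(out_dir, "network_halfperiod_t.tsv"),
                      list(seed = seed))
  }

  if ("regional" %in% stages) {
    log_stage("regional")
    gm_drug <- group_mean_profile(study$drug_profiles)
    ppc <- post_pre_change(gm_drug)
    cpl_div <- regional_coupling(gm_drug, study$diversity_drug)
    len_i <- min(length(windowed_mean(gm_drug$global, 60, gm_drug$tr_seconds)),
                 length(study$intensity))
    cpl_int <- regional_coupling(gm_drug, study$intensity[seq_len(len_i)],
                                 windowed = TRUE)
    rmap <- need("receptor_maps", "regional")[[1]]
    nulls <- build_spin_nulls(need("coords", "regional"),
                              n_spins = n_spins, seed = seed + 3)
    assoc <- lapply(list(post_pre = ppc, diversity = cpl_div,
                         intensity = cpl_int),
                    receptor_association, rmap = rmap, nulls = nulls)
    pbh <- bh_correct(vapply(assoc, `[[`, 0, "p_spin"))
    res$regional <- list(post_pre = ppc, coupling_diversity = cpl_div,
                         coupling_intensity = cpl_int,
                         association = assoc, p_bh = pbh, nulls = nulls)
    tab <- data.frame(metric = names(assoc),
                      rho = vapply(assoc, `[[`, 0, "rho"),
                      p_spin = vapply(assoc, `[[`, 0, "p_spin"),
                      p_bh = pbh)
    write_tsv_sidecar(tab, file.path(out_dir, "receptor_association.tsv"),
                      list(n_spins = n_spins, seed = seed))
  }

  if ("dominance" %in% stages) {
    log_stage("dominance")
    if (is.null(res$regional)) stop("stage 'dominance': requires stage 'regional'")
    maps <- need("receptor_maps", "dominance")
    cm <- maps[[1]]$cortical_mask
    X <- vapply(maps, function(m) m$density[cm], numeric(sum(cm)))
    doms <- lapply(list(post_pre = res$regional$post_pre,
                        diversity = res$regional$coupling_diversity,
                        intensity = res$regional$coupling_intensity),
                   function(y) dominance_analysis(X, y[cm]))
    res$dominance <- doms
    imp <- vapply(doms, `[[`, numeric(ncol(X)), "importance_pct")
    write_tsv_sidecar(imp, file.path(out_dir, "dominance_importance.tsv"),
                      list(seed = seed))
  }

  if ("pksim" %in% stages) {
    log_stage("pksim")
    if (is.null(res$energy)) stop("stage 'pksim': requires stage 'energy'")
    tr <- study$placebo_profiles[[1]]$tr_seconds
    grid_s <- seq(-inj * tr, (M - inj) * tr, by = tr / 2)
    conc <- simulate_concentration(pk, grid_s)
    fit <- fit_alpha_grid(study$bold$placebo, res$energy$group_mean_drug,
                          study$A_s, conc, study$receptor_maps[[1]],
                          grid = alpha_grid)
    res$pksim <- list(conc = conc, fit = fit)
    write_tsv_sidecar(rbind(alpha = as.numeric(names(fit$distances)),
                            distance = fit$distances),
                      file.path(out_dir, "alpha_grid.tsv"),
                      list(best_alpha = fit$alpha, seed = seed))
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("controlenergy")),
    stages = stages, seed = seed, n_perm = n_perm, n_spins = n_spins,
    state_norm = state_norm,
    n_subjects = length(study$drug_profiles),
    n_transitions = M, injection_volume = inj)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(res)
}
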