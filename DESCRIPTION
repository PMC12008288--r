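Package: controlenergy
Title: Time-Resolved Network Control Energy Analysis of Brain Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes minimum control energy trajectories over sequences of
    regional BOLD states evolving on a weighted structural connectome, under
    uniform or time-varying control strategies. Provides Lempel-Ziv (LZ76)
    signal diversity estimation from epoched electrophysiological recordings
    with hemodynamic alignment to the fMRI grid, cluster-based paired
    permutation tests over time, permutation Spearman correlations with
    optional covariate control, spatial-autocorrelation-preserving spin
    permutation nulls for cortical map associations, dominance analysis of
    receptor-map predictors, and an effect-compartment pharmacokinetic
    simulation that builds a concentration- and receptor-weighted control
    schedule to predict drug-condition energy from placebo data. A synthetic
    data generator emulates the statistical structure of a
    pharmaco-fMRI/EEG study so the full pipeline runs and is validated
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
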