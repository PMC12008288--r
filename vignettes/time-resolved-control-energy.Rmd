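---
title: "Time-resolved network control energy: models, assumptions, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Time-resolved network control energy: models, assumptions, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(controlenergy)
```

## The model

`controlenergy` treats a sequence of regional BOLD volumes as a trajectory
through an activational landscape, and asks how much exogenous input a
linear network system would need to reproduce each step of that trajectory.
The dynamics are linear time-invariant,

$$\dot{x}(t) = A\,x(t) + B\,u(t),$$

where $x(t)$ is the vector of regional activations, $A$ is a stabilized
version of the weighted structural connectome, $B = \mathrm{diag}(v)$
assigns each region's input authority (the *control strategy*), and $u(t)$
is the input. For each pair of adjacent volumes $(x_0, x_f)$ the minimum
control energy is

$$u^*(t) = \arg\min \int_0^T u^\top(t)\,u(t)\,dt
\quad\text{s.t. } x(0)=x_0,\; x(T)=x_f,$$

with per-region energy $E_i^* = \int_0^T u_i^*(t)^2\,dt$ and global energy
$E_{\min} = \sum_i E_i^*$. The closed-form solution goes through the finite
horizon controllability Gramian
$W_T = \int_0^T e^{As} B B^\top e^{A^\top s}\,ds$:
$u^*(t) = B^\top e^{A^\top (T-t)} W_T^{-1} d$ with
$d = x_f - e^{AT} x_0$, and $E_{\min} = d^\top W_T^{-1} d$.

Key modelling assumptions to keep in mind:

* **Linearity.** Real BOLD dynamics are not linear; the energy is a
  model-based descriptor, not a biophysical quantity. Its value is in
  *relative* comparisons (conditions, time-points, regions) under a fixed
  $A$ and $T$.
* **A common structural scaffold.** One symmetric connectome (here a
  population-average-style matrix) serves all subjects; individual
  differences in anatomy are not modelled.
* **Adjacent-volume transitions.** Each transition spans one TR with a
  nominal horizon $T = 1$ (arbitrary units, the conventional choice).
  Energies scale smoothly with $T$; comparisons are made at fixed $T$.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `stabilization.c` (`stabilize()`) | 1 | spectral shift | $A_s = W/(\lambda_{\max}(W)+c) - I$ makes all modes decay; $c$ sets the slowest rate $-c/(\lambda_{\max}+c)$. The normalization is the standard one in the continuous-time network-control literature; it is exposed because it is a convention, not a measurement. |
| `T` (`control_config()`) | 1 | a.u. | Horizon per transition. |
| `integration_steps` | 1001 | — | Grid for explicit trajectory integration of $u^*(t)$; odd so the midpoint exists. At $T=1$ and stable spectra this resolves the integrand to ~1e-6 relative (verified against the closed form). |
| `window_seconds` (`windowed_mean()`) | 60 | s | Aligns energy with per-minute intensity ratings. Trailing partial windows are dropped: a mean over fewer samples would be noisier than the rest of the series and bias the last rating window. |
| `alpha` (`build_schedule()`) | grid `[1,10,...,70]` | — | Scales how much control the drug adds; calibrated by grid search against the empirical drug-condition energy series (Euclidean distance over the full series by default; post-injection-only via `post_only`). |
| `n_perm`, `n_spins` | 10000 | — | Permutation counts for inferential procedures; the add-one convention bounds p away from zero. |

## State normalization variants

`normalize_states()` implements four amplitude-normalization schemes
(radial, L2, distance, double) used to separate the contribution of state
*magnitude* from state *direction* in energy differences. Radial
normalization anchors $x_0$ and rescales $x_f$ along $x_f - x_0$ to unit
separation; this matches the definition of final states being unit distance
from initial states, and implies a volume is normalized differently in its
role as a target versus as the next transition's origin. Pairs with exactly
zero separation are an error rather than being skipped silently — exact ties
in continuous data indicate an upstream problem, and the synthetic generator
never produces them.

## Signal diversity

The LZ76 operation implements the Lempel–Ziv exhaustive-history parse of a
mean-binarized epoch. Binarization thresholds *strictly above* the epoch
mean (ties map to 0) — deterministic and the common convention. Counts are
averaged across channels per epoch and left unnormalized. For alignment to
the fMRI grid, the epoch-rate series is convolved with a canonical
double-gamma HRF (peak 6 s, undershoot 16 s, ratio 1/6, 32 s support,
sampled at the epoch rate) and block-averaged onto the volume grid; with
2-s epochs at TR = 2 s the block factor is one, so epoch $k$ maps to volume
$k$. The HRF shape and registration offset are conventions (exposed as
arguments), because no single shape is canonical across cortex.

## Inference

* **Cluster-based paired permutation test.** Per-time-point paired t
  statistics are thresholded at the two-tailed $t$ critical value at
  $\alpha$; maximal supra-threshold runs form clusters scored by mass (sum
  of t). The null is the maximum absolute cluster mass over per-subject
  sign flips, pooling both tails (a max-statistic correction). All-zero
  difference columns are assigned $t = 0$.
* **Permutation Spearman.** Two-sided add-one p over permutations of `y`.
  With a covariate, ranks of both variables are residualized on the ranked
  covariate before correlating; the permutation acts on the residualized
  values. If residual variance falls to rounding-noise level (covariate
  carries all the variance), the correlation is reported as exactly 0.
* **Spin nulls.** Uniform random 3D rotations (QR of a Gaussian matrix with
  determinant forced positive) of unit-sphere parcel centroids; each parcel
  takes the value of the nearest rotated parcel (duplicates allowed). Only
  cortical parcels participate — subcortex cannot be spun — so
  subcortex-inclusive correlations are reported without spin p-values.
* **Dominance analysis.** All $2^p - 1$ OLS submodels; a predictor's total
  dominance averages its $R^2$ increment over subset sizes. Increments use
  raw $R^2$ (the canonical algorithm); the full model's adjusted $R^2$ is
  reported alongside, and an adjusted-increment variant is available via
  `use_adjusted = TRUE`. Percentages are normalized by the summed
  dominances, which equals the full-model raw $R^2$, so they always total
  100.

## Pharmacokinetically-informed control

`simulate_concentration()` solves a linear mammillary compartment model
with a zero-order infusion and a first-order effect compartment
($\dot{C_e} = k_{e0}(C_p - C_e)$) by exact matrix-exponential propagation
over each piecewise-constant-input interval — no ODE integration error. The
default parameter set is **synthetic**: a documented two-compartment
configuration with distribution/elimination on the minutes timescale of a
short-acting intravenous psychedelic. To reproduce a published population
model, pass its estimates to `pk_params()` or import its curve with
`concentration_series()`.

The time-varying control schedule follows
$v(t) = 1 + \alpha\,(\tilde{c}(t) + \tilde{\rho})$ post-injection
(additive mode, the default), or
$v(t) = 1 + \alpha\,\tilde{c}(t)\,\tilde{\rho}$ (multiplicative mode),
with $\tilde{c}$ the concentration rescaled to peak 1 and $\tilde{\rho}$
the receptor density rescaled to mean 1. Both modes are provided because
the two published descriptions of the combination differ; the additive
form is the default as the printed equation. Two further conventions were
genuinely open and are resolved as follows:

* The additive form with zero concentration would still give
  $v = 1 + \alpha\tilde\rho \ne 1$ before the injection, contradicting the
  uniform pre-injection strategy; the schedule therefore applies the
  formula to post-injection transitions only.
* Concentration (ng/mL) and receptor density (Bmax, a.u.) have
  incommensurate units; the peak-1 / mean-1 normalizations above make
  $\alpha$ dimensionless and are exposed as the place to change this.

Because the schedule only ever *adds* control ($v \ge 1$ with equality
pre-injection), predicted energy is non-increasing in $\alpha$ — enlarging
the feasible input set can never raise a minimum. The grid search therefore
finds the $\alpha$ whose energy reduction best matches the empirical drug
series.

## The synthetic study generator

`synth_study()` emulates the statistical structure the analysis assumes,
not the biophysics of the brain:

* a modular weighted connectome (seven cortical modules + subcortex,
  distance-dependent weights);
* spatially autocorrelated receptor maps from a Gaussian process on the
  unit sphere (tunable smoothness, verified with Moran's I);
* paired BOLD series per subject: a stationary AR(1) process coupled
  through the connectome, with the drug condition applying a
  post-injection multiplicative amplitude damping
  $s_i(t) = 1 - \beta_s\,g(t)\,(\gamma \tilde\rho_i + (1-\gamma))$, where
  $g(t)$ is a difference-of-exponentials gate shaped like an
  effect-compartment curve;
* a diversity series inversely coupled to the global energy and a
  discretized 0–10 rise-and-decay intensity curve, zero pre-injection.

The drug effect enters as amplitude damping deliberately: un-normalized
control energy scales quadratically with state magnitude, so the effect
direction (drug energy < placebo post-injection) is analytically
predictable and recovery tests have a well-specified truth. The two
conditions use independent innovation streams — paired difference tests
need within-pair variability, which literally shared noise would remove —
and everything is deterministic given the seed.

What passing tests on this generator do **not** show: robustness to
hemodynamic confounds, head motion, scanner drift, non-stationarity,
scrubbing artifacts, or mis-specified connectomes. Those live upstream of
this package's scope.

Default generator geometry mirrors the study design the package targets
(116 regions of which 100 cortical, 14 subjects, 840 volumes at TR = 2 s,
injection after volume 240). The test suite runs reduced geometries
(typically 16–32 regions, 60–300 volumes, 3–14 subjects) chosen so each
property is tested at meaningful power while the default suite stays fast;
the end-to-end recovery experiments keep the study's 14-subject sample
size, since paired-test power is what those checks exercise.

## Numerical choices

* **Gramian.** Computed by the Van Loan block identity — one matrix
  exponential of the $2N \times 2N$ block $[[-A, BB^\top],[0, A^\top]]$ —
  rather than quadrature. A trapezoidal quadrature implementation survives
  in the test helpers as an independent oracle.
* **Bulk energies.** The stabilized connectome is symmetric, so
  `energy_timeseries()` uses the eigendecomposition of $A$ for exact
  regional energies,
  $E_i = b_i^2\,[U (K \circ cc^\top) U^\top]_{ii}$ with
  $K_{jl} = (e^{(\lambda_j+\lambda_l)T}-1)/(\lambda_j+\lambda_l)$ and
  $c = U^\top W_T^{-1} d$ — no quadrature error, and the Gramian is
  factorized once per unique schedule column (once in total for uniform
  control). `min_energy_transition()` keeps the explicit
  grid-and-trapezoid route, and the two paths are cross-checked to 1e-6
  relative in the tests. Non-symmetric operators fall back to the explicit
  route with complex eigenpropagation.
* **Conditioning.** Gramians with condition number above 1e12 trigger a
  warning and proceed with a symmetric (Cholesky) solve.
* **Tie-breaks and degenerate inputs.** Binarization ties go to 0;
  zero-distance state pairs, zero-norm states, constant correlation inputs
  and singular designs raise errors instead of producing silent NaNs.
* **Connectome symmetrization.** Asymmetries up to 1e-8 (file round-off)
  are averaged; anything larger is an error so upstream bugs are not
  hidden.

## Interfaces

This is an R-native analysis package: the exported functions,
`run_pipeline()` (which orchestrates all stages and writes TSV/JSON results
with a manifest), and `scripts/acceptance.R` are the intended entry points;
no shell CLI is shipped. All file outputs are flat TSV with JSON sidecars
recording parameters and seeds, so results remain inspectable and
language-agnostic.

## Known limitations

* Energies depend on the stabilization convention and $T$; only contrasts
  within a fixed configuration are interpretable.
* The time-resolved design is noise-sensitive; the package follows the
  group-level-first strategy (subject-level variants exist but are noisier).
* `windowed_mean()` drops a trailing partial window, so a 28-minute scan at
  TR = 2 s yields 27 complete windows against 28 per-minute ratings; the
  alignment trims both series to their common length.
* With 240 pre-injection volumes there are only 239 strictly pre-injection
  transitions, so the "8 minutes each side" change metric uses the largest
  equal count available on both sides (239); the transition that spans the
  injection belongs to neither window.
* The spin-null nearest-neighbour reassignment allows duplicates; for
  published-atlas work, precomputed permutation indices can be supplied to
  `spin_test()` via a `spin_nulls`-shaped object.
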