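---
title: "Methods: simulation models, estimators and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulation models, estimators and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lysodyn)
library(dplyr)
```

`lysodyn` quantifies endo-lysosomal function from two experimental readouts:
live-cell videos of fluorescently labelled lysosomes (single-particle
tracking and motility statistics), and bulk measurements of lysosomal
degradative capacity (two-channel DQ-BSA imaging, plate-reader cathepsin
activity, and label-free proteomics of lysosome-enriched fractions). Every
pipeline stage has a paired synthetic-data generator with known ground
truth, so each estimator can be validated without raw microscopy data. This
vignette documents the models, the estimators, and the reasoning behind the
default parameters.

## The two-pool motility model

Lysosomes in cultured neurons separate into a near-immobile pool (largely
perinuclear, caged by the cytoskeleton) and a mobile pool undergoing
microtubule-based directed transport. `simulate_tracks()` draws each track
from the mobile pool with probability `p_mobile` and simulates:

* **stationary pool** — pure Brownian motion: per-frame Gaussian steps with
  per-axis standard deviation $\sqrt{2 D_s \,\Delta t}$,
  `d_stationary = 1e-4` µm²/s by default (sub-resolution jitter);
* **mobile pool** — a persistent random walk: a heading that evolves by von
  Mises increments with concentration `persistence_kappa`, advancing
  `speed_mobile * dt` per frame, superposed on Brownian diffusion with
  `d_mobile`.

Parameter defaults and rationale:

| parameter | default | unit | rationale |
|---|---|---|---|
| `dt` | 0.01 | s | fast acquisition at 100 frames/s; see below |
| `n_frames` | 100 | — | a typical 1 s burst acquisition |
| `speed_mobile` | 1 | µm/s | the scale of motor-driven organelle runs |
| `persistence_kappa` | 50 | — | heading decorrelation time ≈ `kappa * dt` = 0.5 s, the scale of directed run durations; at 10 ms frame spacing directed runs are nearly straight frame-to-frame |
| `d_stationary` | 1e-4 | µm²/s | caged jitter well below the mobility threshold |
| `d_mobile` | 0.005 | µm²/s | residual wobble on top of directed motion |

**On `dt = 0.01` s.** Reported acquisition timings for this kind of
experiment are often internally inconsistent (frame counts, rates and total
durations that cannot all hold simultaneously). The package therefore fixes
a self-consistent default — 100 frames at 100 frames/s (1 s) — and treats
absolute velocity/MSD magnitudes as simulation-defined; analyses aimed at
biology compare *relative* contrasts between groups, which are insensitive
to the absolute time base.

**On `persistence_kappa = 50`.** With a heading decorrelation time much
shorter than the acquisition, a "mobile" track becomes effectively
diffusive and its net displacement can drop below the immobile threshold,
biasing the classified mobile fraction. A persistence time of ~0.5 s at
`dt = 0.01` keeps mobile tracks unambiguously mobile over a 1 s
acquisition, which is also the physically sensible regime for
microtubule-guided runs sampled at 10 ms.

## Video rendering

`render_video()` turns tracks into a calibrated image stack. Each spot is a
pixel-*integrated* Gaussian point-spread function (differences of normal
CDFs over pixel boundaries, not point samples), so total flux is conserved
and sub-pixel positions are meaningful. Noise follows the standard sCMOS
model: Poisson photon noise on spot amplitude and background plus Gaussian
read noise (`read_noise_sd`). Setting `noise = FALSE` gives the
deterministic expectation, used by flux-conservation and centroid tests.
Rendered values are clipped at the 16-bit ceiling with a warning.
Coordinates use `x = column`, `y = row`, with physical position
`(index + 0.5) * pixel_size` so that pixel centres, not corners, carry the
coordinates.

## Spot detection

`detect_spots()` follows the classical small-bright-object protocol:

1. **Disk median filter** (radius 2 px) to remove hot pixels. This is a
   true disk neighbourhood median implemented with a vectorised
   odd–even-transposition sorting network, because the commonly available
   square-window implementations clamp intensities to [0, 1].
2. **Rolling-ball background subtraction**, implemented as grayscale
   opening (erosion then dilation) with a disk of radius 5 px, subtracted
   from the median-filtered frame and clamped at zero.
3. **Scale-normalised Laplacian-of-Gaussian** response at
   $\sigma = (d/p) / (2\sqrt{2})$ where `d` is `spot_diameter` (default
   0.6 µm, the scale of a lysosome) and `p` the pixel size. Detection
   requires `spot_diameter >= 2 * pixel_size` (Nyquist), otherwise an
   error is raised rather than returning unreliable positions.
4. **Robust threshold**: local maxima must exceed
   `threshold_k * 1.4826 * MAD` of the preprocessed frame (default `k = 5`),
   a scale estimate immune to the spots themselves.
5. **Sub-pixel localisation** by 3×3 quadratic interpolation around each
   maximum, and per-spot area from the half-maximum connected component.

## Particle linking

`link_spots()` performs frame-to-frame assignment by *exact*
maximum-weight bipartite matching (via `igraph`), with edge weights
$M - d^2$ for an offset $M$ large enough that the number of matches
dominates and, among maximum matchings, total squared displacement is
minimised. This equals the exhaustive-enumeration optimum (verified in the
test suite on random instances). Candidate links are gated at
`max_link_distance` (default 0.5 µm per frame step); gap closing across up
to `max_gap` missing frames scales the gate with the elapsed time. Tracks
shorter than `min_track_length` (default 5) are discarded.
`evaluate_tracking()` scores recall, precision and identity accuracy (the
fraction of ground-truth frame-to-frame links carried by a single detected
track) against simulated truth.

## Motility statistics

`track_metrics()` computes per track: path length, net and maximum
displacement, straightness (net/path, 0 for a degenerate path), mean
velocity (path length over elapsed time), mean squared displacement
(`from_origin`: the scalar mean of squared displacements from the first
point; `time_averaged`: the MSD curve over lag times), and the initial-to-
final displacement angle (with an optional `flip_y` for image-convention
axes). `classify_mobility()` applies the immobile rule: a track is
immobile when its displacement is strictly below 0.2 µm; displacements of
exactly 0.2 µm count as mobile. `ensemble_msd()` fits the diffusion
coefficient through the origin of the ensemble time-averaged MSD,
$\mathrm{MSD}(\tau) = 4 D \tau$.

## Resampling and group comparison

`bootstrap_parameter()` draws `n_boot = 1000` resamples with replacement
and reports the percentile interval (type-7 quantiles). The percentile
interval is near-nominal for location parameters at the sample sizes this
package targets (hundreds to tens of thousands of pooled per-track
measurements); for very small samples it is known to undercover slightly.

`compare_groups()` implements the protocol decision tree: per-group
normality by Shapiro–Wilk (n < 50) or Kolmogorov–Smirnov against the
sample's own moments (n ≥ 50); `two_group` designs use an unpaired
two-tailed Student's t-test; `one_way` designs use ANOVA when all groups
pass normality and otherwise Kruskal–Wallis followed by `dunn_test()`
(all-pairs z-tests on mean ranks with tie correction and Bonferroni
adjustment — implemented from the rank-sum formulas); `two_way` fits a
two-factor ANOVA with interaction. `rose_histogram()` (equal-width,
left-closed bins from 0°) and `raincloud_summary()` (type-7 quartiles,
Tukey whiskers, Gaussian KDE with Silverman's bandwidth) provide the
deterministic tables behind the plotting helpers.

## Moderated differential expression

`build_matrix()` log2-transforms raw intensities (non-positive values
become missing) and drops proteins observed fewer than `min_obs_per_group`
times in any group. `moderated_ttest()` implements the empirical-Bayes
moderated t-test: per-protein pooled two-sample statistics are shrunk
toward a scaled inverse chi-square variance prior $(d_0, s_0^2)$ estimated
across proteins by moment matching on $\log s^2$ (with Newton inversion of
the trigamma function); the posterior variance is
$\tilde s^2 = (d_0 s_0^2 + d s^2)/(d_0 + d)$ and the moderated t has
$d_0 + d$ degrees of freedom. Forcing `df_prior = 0` recovers the ordinary
pooled t-test exactly; with fixed hyperparameters the statistics agree
with the `limma` reference implementation to 8 decimals (cross-checked in
the test suite, where `limma` serves only as an oracle). P values are
Benjamini–Hochberg adjusted across proteins.

Two cutoff regimes are built in: **stringent** (p < 0.05 and |log2FC| ≥ 1)
and **lenient** (p < 0.05 and |log2FC| ≥ 0.5), with `p_basis` selecting raw
(default) or BH-adjusted p values. Downstream set analysis includes
exclusive (upset-style) and pairwise overlaps, cross-referencing against a
curated identifier list (case-insensitive), and exact hypergeometric
over-representation (`ora_hypergeometric()`, upper-tail
$P(X \ge k)$, BH-adjusted across sets).

The paired generator `simulate_intensity_matrix()` plants a fraction
`frac_de` of ±`effect_log2fc` shifts on a matrix whose per-protein
variances are drawn from the same scaled inverse chi-square family the
estimator assumes (`df_prior_true = 4`, prior *scale* `s0_true = 0.25`,
i.e. prior variance 0.0625), so hyperparameter recovery is testable.

## Image-based and plate-based assays

`segment_cells()` segments nuclei by Otsu threshold, hole filling and
watershed splitting on the distance transform, then grows cell territories
by nearest-nucleus (Voronoi) propagation capped at `max_radius_um` (default
30 µm). `per_cell_ratio()` background-corrects the uptake and
degraded-probe channels (image mode by default, or rolling-ball) and
reports the per-cell `degraded / uptake` ratio — proteolytic output per
unit endocytic input — excluding cells with non-positive corrected uptake.
The ratio is invariant to detector gain, which is the point of the
two-channel design.

`cathepsin_activity()` averages duplicate wells, subtracts the blank and
normalises to incubation time and protein load:
$(F - F_{\text{blank}})/(\text{min} \cdot \text{mg})$ in RFU/min/mg.
Inhibitor-control wells define the specific activity; negative corrected
values are reported as 0 and flagged rather than propagated.

## Generator realism limits

The generators are deliberately minimal: tracks do not switch between
pools mid-trajectory; cells are round and non-overlapping; photobleaching,
focus drift, stage drift and spot-merging are not modelled; proteomics
missingness is only via non-positive intensities, not
intensity-dependent dropout. These choices keep the ground truth exact.
Consequences: identity-accuracy figures from simulations are upper bounds
for crowded real fields, and the DQ-BSA round trip validates the ratio
arithmetic, not segmentation robustness to irregular morphologies.

## Problem sizes and runtime

Default problem sizes are package choices scaled for a desk machine: 500–
1000 simulated tracks per group (binomial/bootstrap standard errors a few
percent), 2000-protein matrices with 4 samples per group, 256 px rendered
fields with 20–30 spots, and 20–50 cell DQ-BSA fields. The full test
suite runs in a few minutes on one CPU; `scripts/acceptance.R` recomputes
the headline quantities in under a minute.

## A minimal worked chain

```{r chain}
p <- motility_params(p_mobile = 0.6)
tracks <- simulate_tracks(p, n_tracks = 200, seed = 7)
metrics <- track_metrics(tracks)
summarise(metrics,
          mobile_fraction = mean(mobile),
          mean_velocity = mean(mean_velocity_um_s))
```
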