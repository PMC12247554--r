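---
title: "Detecting global-signal-induced bias in fMRI motion estimates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting global-signal-induced bias in fMRI motion estimates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Rigid-body motion parameters estimated by intensity-based volume
registration are the standard descriptors of head motion in resting-state
fMRI, and they are routinely regressed out of the data before functional
connectivity (FC) analysis. Registration, however, minimizes an intensity
cost: any widespread intensity fluctuation that overlaps spatially with the
registration's sensitivity pattern leaks into the motion estimates. The
global BOLD signal (GS) — the spatial mean of the percent-change signal over
the brain — is exactly such a fluctuation. Because its voxelwise coupling
map is not symmetric about the head centre (it is stronger superiorly and
posteriorly), the GS pushes the estimated y- and z-translations coherently,
producing motion estimates that are temporally correlated with neural
activity. Regressing those biased estimates out of the data then removes
real signal and attenuates FC, more strongly in runs (and groups) with a
large GS amplitude and little true motion.

`gsbias` implements the full detection and characterization pipeline for
this effect on synthetic multi-echo data with known ground truth:

1. a **two-echo signal model**: BOLD effects scale with echo time while
   motion does not, so the per-axis difference of motion estimates from two
   echoes, `dm = me2 - me1`, cancels true motion and isolates BOLD-weighted
   bias;
2. a **per-run significance test** of `r(dm, GS)` against empirical nulls
   built by pairing the GS of one run with the `dm` of every other run
   (`n(n-1)` samples for `n` runs), with Bonferroni control across runs;
3. a **spatial decomposition** that approximates `r(dm, GS)` from the GS
   beta-coefficient maps and the registration derivative images,
   `r(dm, GS) ~ (||gs|| / ||dm||) (b_e2' d_e2 / ||d_e2||^2 -
   b_e1' d_e1 / ||d_e1||^2)`, explaining the bias as a broken-symmetry
   inner product;
4. an **FC impact analysis**: ROI-ROI correlations after motion regression
   with echo-1 vs echo-2 parameters (censored at FD > 0.2 mm), their
   Fisher-z differences `dz`, stratification over FD-by-aGS groups, and a
   two-group (young-like vs old-like) comparison.

## The generative model

The phantom is a smooth-edged ellipsoid (default semi-axes 36 x 42 x 30 mm
in a 32 x 32 x 24 grid of 3 mm voxels, matching a whole-head EPI field of
view at desk scale) with baseline intensity `s0 = 1000`, modulated by a
fixed smooth internal intensity pattern (+-20%, a product of cosines, even
in every axis so the phantom's mirror symmetries are preserved) that plays
the role of gray/white/CSF tissue contrast — without internal structure,
in-plane rotation would be nearly unobservable to an intensity-based
registrar, which no real EPI volume is. Baseline relaxation rate is
`R2* = 0.022 /ms` (T2* about 45 ms, a typical cortical value at 3 T). Each frame and echo is rendered from the full mono-exponential
signal law

```
S_i(v, t) = s0(v) * exp(-TE_i * [R2*(v) - c(v) * gs(t)])
```

followed by a rigid transform of the volume by that frame's ground-truth
motion and additive Gaussian noise. Simulating the exponential rather than
its linearization makes the small-signal percent-change relation
`dS/S ~ TE_i * c(v) * gs(t)` a *testable property* (the suite checks the
echo-2 : echo-1 amplitude ratio equals `TE2/TE1 = 30/13.7`).

The coupling map is `c(v) = base_c * max(0, 1 + a_y * yhat + a_z * zhat)`
with `yhat, zhat` in `[-1, 1]` (+y posterior, +z superior). `a_y = a_z =
0.5` gives the superior/posterior weighting that drives Ty/Tz bias;
`a_y = a_z = 0` gives a symmetric map for specificity checks. The default
`base_c = 1e-4 /ms` per unit driver yields an echo-2 GS amplitude of about
0.3% signal change, a typical resting-state global fluctuation. The driver
is frequency-domain low-passed Gaussian noise (default cutoff 0.1 Hz at
TR = 3 s) standardized exactly to mean 0, SD 1, so the coupling map alone
controls amplitude. The noise SD default of 7.5 gives a temporal SNR of
about 70 at the echo-2 brain mean, in the usual range for 3 mm 3 T EPI.

Ground-truth motion profiles are `none`, `drift` (smoothed random walk),
`spikes` (isolated displaced frames) and `mixed`; the reference frame never
moves. What the generator does **not** emulate: EPI distortion, slice
timing, physiological noise, spin history, receive-coil inhomogeneity and
multi-site differences. Passing tests therefore demonstrate the internal
consistency of the estimator-bias mechanism, not its magnitude in any real
dataset.

## The registration estimator

`register_volume` estimates the six movement-of-volume parameters `m`
(Rx, Ry, Rz in degrees, Tx, Ty, Tz in mm; rotations about the grid centre
composed as `Rx %*% Ry %*% Rz`) by Gauss-Newton least squares on
`sum_v (T(ref; m)(v) - vol(v))^2` with **uniform weights** — every voxel
counts equally, which is the configuration whose bias the package studies.
Design choices worth noting:

* **Solving for the movement directly.** Estimating `m` such that the moved
  reference matches the frame is equivalent, to first order, to estimating
  the aligning transform of the frame and negating it; solving directly
  avoids the second-order error of negating rigid parameters (rigid
  inverses are not parameter negations), which matters at the 0.05 mm/deg
  recovery tolerance the tests impose.
* **Frozen reference Jacobian with secant refinement.** The Jacobian
  columns are the six central-difference derivative images of the
  reference volume (steps 2.1 mm / 0.4 deg, the values a standard
  registrar derives for 3 mm voxels), computed once per run and shared
  across frames. The frozen fixed point is exact in the zero-residual
  limit but carries a quadratic parameter bias under combined rotations;
  when the converged estimate exceeds 0.15 mm/deg on any axis the
  Jacobian is therefore recomputed once at the estimate and the solve
  refined (small-motion frames skip this entirely). A step that increases
  the SSE is rejected — triggering one mid-run re-linearization — and a
  sub-tolerance rejected step counts as convergence at the noise floor.
  `refresh_jacobian = TRUE` recomputes the Jacobian every iteration for
  verification (the tests confirm both paths agree to 0.02).
* **Cubic interpolation** (Catmull-Rom, interpolating, zero-padded) for all
  warps; exact at integer-voxel shifts, which several bit-exactness tests
  exploit. Interpolation order is configurable.
* Frames are initialized from the previous frame's estimate; convergence
  tolerance 0.001 mm/deg, at most 20 iterations.

On the default phantom the estimator recovers injected motion up to
3 mm / 3 deg with per-axis RMSE below 0.05, agrees with a dense SSE-scan
oracle to 0.05 mm on single-axis translations, and — with zero coupling —
produces echo-1 and echo-2 estimates agreeing to better than 0.02 mm/deg,
the premise that licenses reading `dm` as pure bias.

## Preprocessing and the bias statistic

The brain mask is formed from the mean unregistered echo-1 volume (shortest
TE, best SNR) by thresholding at half the 99th-percentile intensity,
keeping the largest 6-connected component and filling interior holes. Each
voxel is normalized to percent change about its temporal mean; the GS is
the in-mask spatial mean of the **registered echo-2** percent-change data.
The GS and every motion series are detrended by projecting out `{1, t,
t^2}` (t scaled to [-1, 1]).

`dm = me2 - me1` is computed per axis and detrended. Optionally the twelve
echo-1 motion regressors (six parameters plus backward-difference
derivatives) are regressed out of both the GS and `dm` first; on biased
synthetic runs this *raises* the median `r(dm, GS)` because it removes
motion artifacts from the GS, reproducing the direction seen with the
corresponding analysis on real data.

Per-run empirical p-values use the add-one estimator
`(1 + #{|r_null| >= |r_obs|}) / (1 + n_null)`, which cannot return 0. The
**significance decision**, however, compares `|r_obs|` with the
`1 - alpha/n` empirical quantile of `|null|` — the r-value corresponding to
the Bonferroni-corrected threshold assessed from the null distribution.
The two rules coincide for large nulls, but for a 20-run cohort the null
has only 380 samples and the smallest attainable add-one p (1/381) already
exceeds `0.05/20`: a p-value comparison would have zero power by
construction, while the quantile rule retains it. This is the package's
resolution of a genuine small-sample corner of the method; at 602 runs
(null size 361,802) the distinction vanishes.

## The spatial approximation and its two beta-map forms

The decomposition approximates `r(dm, GS)` by a scale factor
`||gs||/||dm||` times the difference of per-echo inner products
`b' d / ||d||^2`. Two forms of the GS coupling map `b` are computed:

* `beta_e*`: the **percent-change** beta map over the brain mask — the map
  form used for visualization and mechanism figures (positive across the
  "cortex", higher superiorly/posteriorly under asymmetric coupling).
* `beta_raw_e*`: the **raw-intensity** beta map (regression of the raw
  unregistered data on the GS) over the full grid. The estimator itself
  sees raw intensities at every voxel, and its first-order per-axis
  response is exactly `d' beta_raw / ||d||^2` per unit GS; the percent and
  raw forms differ by the voxelwise factor `meanI(v)/100`.

On real brains the mean intensity is relatively homogeneous where the
derivative images have support, so the percent form tracks the estimator
well. On the phantom the intensity tapers steeply across the brain edge —
exactly where the derivative images live — and the percent form
underestimates the correlation by roughly a factor of two, while the raw
form reproduces it to a median absolute error of about 0.04 for Tz (the
residual reflecting the neglected cross-axis coupling of the joint
six-parameter solve and the mm-vs-percent scale mixing). The quantitative
fidelity checks therefore use the raw form; both are exported so the
difference is itself inspectable. Under a left-right-symmetric coupling
map the Tx inner products cancel (|approx r| < 0.05), and flipping the
sign of the superior-inferior coupling gradient flips the sign of the Tz
approximation — the broken-symmetry mechanism in its purest form.

## FC impact

ROI signals are spatial means of registered echo-2 percent-change data over
four spherical ROIs (12 mm diameter) placed posterior, anterior, left and
right of the phantom centre, all GS-coupled. FD is computed from echo-1
parameters (translation differences plus rotation arc length at 50 mm, the
radius of the cited formulation), frames with FD > 0.2 mm are censored
*before* regression, and the same keep mask is used for every regressor
variant so `dz` isolates the regressor difference. Pearson correlations are
Fisher-z transformed with `|r|` capped at `1 - 1e-7`.

The cohort preset simulates "young-like" runs (coupling scale log-uniform
on [0.8, 3.0], drift+spike motion amplitude 0.06-0.14 mm) and "old-like"
runs (scale [0.25, 1.0], amplitude 0.15-0.5 mm): GS amplitude spans a wide
range *within* each group, as it does across subjects in resting-state
cohorts, which is what makes the FD-by-aGS stratification informative
rather than a relabelled group split. Runs are split at the median mean-FD
(strictly greater = high motion; ties fall low), then at the within-group
median aGS (the SD of the censored GS). Expected pattern, reproduced by the
acceptance checks: `mean dz < 0` overall (biased regressors remove real
GS-coupled signal), most negative for low-FD/high-aGS runs, closest to zero
for high-FD/low-aGS runs, a significant one-way ANOVA group effect,
near-total shrinkage of `|mean dz|` when the Ty/Tz regressors (the biased
axes) are excluded, and a large negative young-vs-old Cohen's d with a
permutation p at its resolution limit.

## Numerical choices and degenerate inputs

* Empirical p-values can never be 0 (add-one estimator); permutation tests
  use the same estimator.
* `|r|` is capped at `1 - 1e-7` before `atanh`; degenerate ROI pairs stay
  finite.
* Zero-variance series are rejected with explicit errors
  (`pearson_r`, `register_volume` on a constant reference); singular
  registration normal equations name the degenerate axis.
* Negative instantaneous R2* during rendering (very strong coupling) is
  clamped to zero with a warning and a count.
* Collinear nuisance regressors are dropped with a warning naming the
  columns.
* All randomness flows through explicit seeds; per-stage seeds derive from
  a master seed by a stable integer hash, so every experiment is
  bit-reproducible.

## Problem sizes

The synthetic study conditions are K = 200 frames on the 32 x 32 x 24 grid.
The power/specificity experiments use 20 runs per cohort, the FC cohort 24
runs, and the null-calibration experiment 510 series-level evaluations
(30 runs x 17 cohorts); the demonstration scripts under `analysis/` use
smaller cohorts (4-12 runs) to stay interactive. Permutation defaults are
10^4 label permutations for the two-group test, with the count configurable
where a larger budget is wanted.

## Known limitations

* The phantom's edge taper is far steeper than a real brain's intensity
  profile; this is why the percent-change form of the spatial approximation
  degrades here (see above) and why absolute bias magnitudes should not be
  read across to real data.
* Only the uniform-weight registration cost is implemented; weighted,
  affine or cross-modal registration is out of scope.
* No physiological noise or distortion processes; the null calibration
  therefore checks the statistics, not robustness to structured artifacts.
* Bonferroni control across runs follows the method being characterized;
  no FDR alternative is provided.
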