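---
title: "Methods: seed-based dynamic functional connectivity variance"
author: "dfcvar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: seed-based dynamic functional connectivity variance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The question and the statistic

Resting-state functional connectivity is usually summarized by one
correlation per region pair, assuming the coupling is stationary over the
scan. dfcvar implements the *dynamic* alternative for seed-based maps: the
seed-to-voxel correlation is recomputed inside short sliding windows, and
the per-voxel variability of those windowed correlations becomes the
statistic of interest. Concretely, for a seed time series $s(t)$ and a voxel
series $y(t)$, windows of length $L$ TRs slide by one TR; within window $k$
the Pearson correlation $r_k$ is computed under Hamming observation weights
$w_i = 0.54 - 0.46\cos(2\pi i/(L-1))$, transformed to
$z_k = \operatorname{atanh}(r_k)$, and the subject's map stores the sample
standard deviation of $z_1,\dots,z_K$ ($n-1$ denominator). With 210 acquired
volumes, 10 discarded and $L = 50$ at TR = 2 s, there are exactly
$K = 151$ windows.

The motivating application is nicotine dependence: six 6-mm spherical seeds
in the insular subdivisions (ventral anterior, dorsal anterior, posterior;
both hemispheres; `insula_seeds()`), whose dFC variability differs between
smokers and non-smoking controls and relates to smoking history.

Two deliberate choices in the core statistic:

* **The Hamming taper enters as observation weights** inside the weighted
  means, variances and covariance — not by pre-multiplying the raw series.
  Pre-multiplication distorts the window means and is not a correlation
  taper. A `rectangular` taper is available through `window_spec()`.
* **Perfect correlations are clipped** to $|r| \le 1 - 10^{-7}$ before
  `atanh`, so noise-free voxels produce $z$-series with zero variance
  instead of infinities.

Maps are not z-standardized across voxels by default; whether the original
toolboxes standardize before group statistics is unstated in the
literature this pipeline follows, so both paths are provided
(`dfc_variance_map(..., standardize = TRUE)`) and the default is the
untouched SD map.

## Preprocessing

`preprocess_bold()` chains: discard the first 10 volumes → ordinary
least-squares removal of 8 confounds (6 motion parameters, white matter,
CSF; intercept included) → ideal frequency-domain bandpass 0.01–0.08 Hz →
6-mm FWHM separable Gaussian smoothing. The published order of the source
pipeline places smoothing before temporal filtering but interleaves a
spatial-normalization step that is out of scope here (synthetic data are
generated on a common grid); the default therefore filters before
smoothing, and `bandpass_last = TRUE` restores the literal published order.
Both the regression and the ideal filter are exact projections, hence
idempotent — a property the tests assert bin-exactly.

Motion quality control excludes a subject when any translation axis
*strictly exceeds* 2 mm or any rotation axis 2 degrees; boundary values
pass. Rotations are taken as given in degrees, with no small-angle
conversion to mm.

## Group inference

`two_sample_t_map()` computes the voxelwise pooled-variance two-sample t
(smokers − controls, df $= n_1+n_2-2$). Pooled rather than Welch: pooled
reproduces the published cohort-table t for exhaled CO (8.29 vs printed
8.293) where Welch gives 8.88.

Cluster-level correction follows Gaussian random field theory.
Smoothness is estimated from the standardized residual fields: per axis,
$\mathrm{FWHM}_i = \Delta_i\sqrt{4\ln 2/\overline{(\Delta u)^2}}$, where
$\overline{(\Delta u)^2}$ is the mean squared neighbor difference of the
unit-variance residual fields (rescaled by $M/\mathrm{df}$ because
standardization fixes each voxel's residual sum of squares at df). The
deliberately simple derivative-variance form is kept without inverting the
Gaussian autocorrelation: the finite-difference bias is ≈ +9% at
FWHM = 2 voxels, while the inversion form degenerates (FWHM → 0) on
unsmoothed noise. The resel count is the in-mask volume divided by the
FWHM product.

`grf_cluster_correction()` then thresholds at the two-tailed voxel level
($u$ = upper $p/2$ t-quantile; a `per_tail` flag spends the full $p$ per
tail instead), clusters each sign separately by face (6-neighbour)
connectivity (18/26 by option), and assigns each cluster of extent $k$ the
classical corrected p:
$$p = 1 - \exp\{-E[m]\,P(N \ge k)\}, \qquad
  P(N \ge k) = \exp(-\beta k^{2/3}),$$
with $E[m]$ the expected cluster count from the expected Euler
characteristic of the **two-sided** $|t|$ excursion set (twice the one-tail
3-D EC density times the resel count) and $\beta$ matched to the expected
extent $E[N]/E[m]$. Using the two-sided $E[m]$ makes the corrected p
control the family-wise rate across both signs jointly; computing it per
tail would double the realized rate under the calibration the tests run.
Monte-Carlo calibration on 500 null smooth t-fields of known 6-mm FWHM
(24×28×24 grid, 3-mm voxels, 10+10 subjects) yields a family-wise rate
within 0.05 ± 0.03; mild conservatism is expected from the high-threshold
approximation on a discrete field.

Brain–behavior analysis (`pearson_with_fdr()`) computes Pearson r between
each surviving cluster's mean dFC variability and each smoking covariate
(years, cigarettes/day, FTCD) across smokers, with Benjamini–Hochberg
correction across *all* (cluster × behavior) pairs in one family — the
family definition is unstated in the source analyses, so the most
conservative all-pairs family is the default and is recorded in the output.

## Classification

`loocv_svm()` runs leave-one-out cross-validation of a linear SVM
(margin cost 1; kernel and cost are unstated in the source design and are
switchable) on cluster-mean features. Features are z-scored with the
training fold's mean/SD only; the held-out subject never influences its
own fold's standardization or fit, a property the tests probe directly.
Class weights are balanced (inverse training-fold frequency) by default:
leave-one-out folds always under-represent the held-out class by one
subject, and without reweighting a label-noise fit drifts toward the
majority class, pushing permuted-label accuracy well below
chance. With balancing the permutation distribution centers
near 0.5, which is what a calibrated null requires; `class_weights =
"none"` disables it. Sensitivity counts smokers as positives. The AUC is
the rank (Mann–Whitney) statistic on pooled held-out decision scores, ties
at half.

`permutation_test()` reshuffles labels only and re-runs the *full* LOOCV
each iteration; p uses the add-one estimator
$(1 + \#\{\mathrm{perm} \ge \mathrm{obs}\})/(1 + n_{\mathrm{perm}})$, so it
is never exactly zero. The study-scale design uses 10,000 iterations; the
bundled analyses use 1,000 (and 49 inside null-calibration replicates),
which resolves the decisions those runs make.

Feature selection note: the source design defines clusters on the full
sample and then cross-validates — a known selection-leakage design. The
pipeline reproduces exactly that ("paper mode"): `run_group_inference()`
on all subjects, then `extract_cluster_features()` + `loocv_svm()`. For a
leakage-free estimate the cluster definition must be re-run inside each
training fold; the building blocks support it, and the caveat matters
whenever the reported accuracy is read as an out-of-sample estimate.

## The synthetic cohort

No raw images are distributed with the source study, so every downstream
stage is exercised on a generator (`sim_config()`, `generate_cohort()`)
whose defaults *are* the study conditions: 31 + 27 subjects, 210 volumes,
TR 2 s, 3-mm isotropic voxels, 10 discarded volumes, 2 mm/2° motion
limits. The grid is desk-scale (24×28×24, an inscribed ellipsoidal
"brain" of ≈6,600 voxels) rather than whole-head; whole-head sizes are
config-selectable but change nothing structurally.

Generative model per subject: each seed sphere carries a band-limited
(0.01–0.08 Hz) unit-variance Gaussian driver $s(t)$ plus white noise
(SD 1); effect-region voxels follow $(a + b\,m(t))\,s(t)$ + noise with
$a = 1$ and $m(t)$ a random-phase sinusoid of period 160 s (zero mean,
unit variance); all other in-mask voxels carry independent 1/f-like noise;
and every in-mask voxel receives a 0.5-scaled random mix of 6 synthetic
motion drifts and 2 AR(1) tissue signals, which are archived so
preprocessing can regress exactly what was injected. The modulator period
was fixed at 160 s because the 100-s analysis window must be able to
resolve the coupling fluctuation (period > window) while several cycles
still fit in the 400-s analyzed run. The modulation amplitude $b$ (0.8 for
smokers, 0.2 for controls by default) maps directly onto dFC variance —
the injected group difference.

Covariates are drawn from Gaussians matched to the published group means
and SDs (age 30.32 ± 6.48 vs 29.37 ± 5.56; education 12.65 ± 2.26 vs
13.70 ± 2.60; CO 15.90 ± 8.98 vs 1.52 ± 0.75 ppm; smoking years
8.87 ± 6.63; cigarettes/day 12.26 ± 8.19; FTCD 5.74 ± 1.36), truncated at
plausible bounds (CO ≥ 6 ppm for smokers, ≤ 3 for controls, matching the
inclusion criteria). Setting `b_sd > 0` and `behavior_rho > 0` gives each
smoker an individual amplitude correlated with smoking years (the
brain–behavior analyses use `b_sd = 0.3`, `behavior_rho = 0.8`, i.e. a
latent coupling stronger than the published r ≈ 0.47 so the stage is
exercised well above threshold at the study's n = 31 smokers).

What the generator does **not** emulate — and therefore what passing tests
cannot show about real data: no hemodynamic response convolution, no
cardiac/respiratory physiology, no anatomy or tissue contrast, no
scanner drift or spatially structured noise, no registration error (all
subjects share one grid by construction), and coupling that fluctuates as
a single sinusoid rather than the irregular multi-scale dynamics of real
BOLD. The pipeline's *statistical* behavior (calibration, recovery,
leakage) transfers; claims about real smokers do not.

## Numerical and degenerate-input choices

* Sphere membership: voxel-center Euclidean distance in mm through the
  affine, inclusive (`<=`); a 6-mm sphere on a 3-mm grid centered on a
  voxel center contains exactly 33 voxels.
* Grids are compared exactly; mismatched affines raise, never resample.
* Zero weighted variance inside a window → the correlation is undefined →
  `NA`, propagated into that voxel's SD.
* Zero pooled variance at a voxel → t is `NA` with a message.
* Rank-deficient confound designs name the collinear columns and stop.
* The ideal bandpass always removes DC, and its passband test is bin-exact,
  so applying it twice is the identity on its image.
* Smoothing kernels are sum-normalized and truncated at 3σ with zero
  padding: constants are preserved away from edges; anisotropic voxel
  sizes are honored per axis.
* All randomness flows from explicit integer seeds; a dataset is a pure
  function of its `sim_config` including `rng_seed`.

## Problem sizes used by the bundled analyses

The recovery and classification analyses use 20 + 20 subjects on the
24×28×24 grid with amplitudes 0.8 vs 0.2; the GRF calibration uses 500
null replicates at 10 + 10 subjects with known 6-mm smoothness; the
brain–behavior replicates use 20 cohorts of 31 smokers + 8 controls on a
16×18×16 grid. These sizes were chosen so each stage's decision (rate
within band, overlap above bound, p below threshold) is resolved with
margin at desk scale; the full-sample workflow in `analysis/` runs the
published 31 + 27 design end to end.

## Known limitations

* Cluster extents at desk scale overshoot the injected region (the
  acceptance run reports the surviving-to-true size ratio, typically ~2):
  6-mm smoothing of a compact effect produces a significant halo, so extent is
  a biased (upward) estimate of the true region size; peak location and
  overlap are the reliable recovery measures.
* The GRF extent null is the classical exponential approximation; it is
  accurate at the 0.005 voxel threshold used here but degrades at lenient
  thresholds.
* The smoothness estimator assumes a stationary Gaussian autocorrelation;
  dFC-variance maps are only approximately so.
* "Paper-mode" feature selection leaks the full-sample cluster definition
  into the cross-validation (see above).
* The permutation test re-runs LOOCV per iteration; at 10,000 iterations
  and 58 subjects that is ~580,000 SVM fits — minutes, not seconds.
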