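---
title: "Predicting facial emotion recognition from resting-state amplitude: models and design choices"
author: "ferpredict"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting facial emotion recognition from resting-state amplitude}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(ferpredict)
```

`ferpredict` implements an individual-level brain-behavior prediction
pipeline for resting-state fMRI: voxel-wise amplitude of low-frequency
fluctuation (ALFF) and its globally normalized form (mALFF),
covariate-adjusted group-difference mapping with Monte Carlo cluster-extent
correction, and relevance-filtered leave-one-out support-vector regression
(SVR) of facial-emotion-recognition (FER) accuracy, assessed by permutation.
The motivating application is a case-control design — first-episode
schizophrenia patients versus healthy controls — where the group-difference
map defines the voxel mask from which fearful-face detection accuracy is
predicted in the patient group.

This vignette explains the models, the conventions chosen where the
methodology leaves room, and what the synthetic cohort does and does not
emulate.  It states no empirical results; the numbers the package produces
come from its tests and from `scripts/acceptance.R`.

## ALFF and mALFF

For a voxel time-series $x_t$, $t = 0, \dots, N-1$, sampled at interval
$\mathrm{TR}$, the discrete Fourier transform at bin $k$ has frequency
$f_k = k / (N \cdot \mathrm{TR})$.  We define the amplitude spectrum as

$$ a_k = \frac{2\,|X_k|}{N}, $$

so that a sinusoid of unit amplitude at an exact bin frequency scores
$a_k = 1$ at that bin.  ALFF is the mean of $a_k$ over the bins in the
closed band $[0.01, 0.08]$ Hz.  Conventions chosen here, each immaterial
after normalization but fixed for reproducibility:

* full detrended series length, no zero-padding, no taper window;
* band inclusion is closed at both endpoints ($0.01 \le f_k \le 0.08$);
* the amplitude scale constant cancels in mALFF, which divides every
  in-mask voxel by the mask-wide mean ALFF, forcing the in-mask mean of the
  resulting map to exactly 1.

Internally the band amplitudes are computed by projecting the series onto
the cosine/sine pair of each in-band bin (a matrix product), which is
algebraically identical to taking the FFT and discarding out-of-band bins
but costs $O(N \cdot K)$ per voxel for $K$ band bins.  The test suite
verifies equality with an independent FFT periodogram to $10^{-10}$
relative error, plus a Parseval identity linking the per-bin amplitudes to
the series variance.

## Subject-level preprocessing

The per-subject order of operations is: drop the first 10 dummy scans,
remove a per-voxel linear trend, smooth each frame with an 8-mm FWHM
Gaussian kernel, optionally regress nuisance covariates, then compute ALFF
and normalize to mALFF.  Published pipelines differ on whether smoothing
precedes or follows detrending and whether ALFF uses the smoothed series;
both orderings are defensible, the listed one is this package's default,
and every stage is independently callable so other orders can be composed.
Spatial smoothing uses a sampled Gaussian truncated at $4\sigma$ with
mirrored boundaries, which conserves constant fields; `fwhm = 0` is the
identity.  Head-motion gating is a strict inequality: subjects qualify only
below 2 mm translation and 2 degrees rotation.

## Group difference map

At every in-mask voxel we fit ordinary least squares of mALFF on
$[\,1,\ \mathrm{group},\ \mathrm{sex},\ \mathrm{age},\ \mathrm{education}\,]$
with covariates mean-centered (centering leaves the group $t$ invariant but
improves conditioning), and take the $t$ statistic of the group coefficient
(positive = patients above controls) with two-sided Student $p$ on
$n - \mathrm{rank}$ degrees of freedom.  With no covariates this reduces
exactly to the pooled two-sample $t$, which the tests verify to $10^{-10}$.

Cluster-extent correction follows the AlphaSim logic: simulate Gaussian
noise volumes on the mask, smooth them to the estimated residual
smoothness, standardize within the mask, threshold two-sidedly at the
uncorrected voxel $p$ (default 0.001), label connected components per sign,
and record each iteration's maximum cluster size.  The minimum significant
extent is the smallest $k$ whose exceedance fraction is at most the target
family-wise $\alpha$ (default 0.05).  Design choices:

* **Smoothness input.**  The Monte Carlo null uses the smoothness
  *estimated from the GLM residuals* — per axis,
  $\mathrm{FWHM} = \Delta \sqrt{-2\ln 2 / \ln \rho}$ with $\rho$ the lag-1
  spatial autocorrelation averaged over residual maps and $\Delta$ the
  voxel size — not the nominal applied kernel.  This matches AlphaSim
  practice: the map's effective smoothness combines acquisition, generator
  and applied smoothing.  Estimates are clamped below at one voxel width.
* **Connectivity.**  Face connectivity (6 neighbors) by default,
  configurable to 18 or 26.  The choice is recorded in the cluster result.
* **Two-sided thresholding with per-sign clustering**, since both
  directions of group difference are scientifically meaningful.
* Clusters are canonically ordered by descending size with lexicographic
  peak-coordinate tie-breaks, so results are invariant to voxel processing
  order.  The voxel threshold (0.001) and the cluster-defining $\alpha$
  are configuration values, not constants.

## Prediction: relevance-filtered LOOCV SVR

The significant clusters define the feature mask.  The model is fit on the
patient group only: the feature matrix holds each patient's mALFF at every
masked voxel.  Before modeling, the Shapiro-Wilk test checks the target's
normality (Pearson correlation is the relevance statistic); deviation
produces a warning, never an abort, since the downstream inference is
permutation-based and does not lean on that assumption.

Each leave-one-out fold refits everything on its $n-1$ training subjects:

1. **Relevance filter** — keep voxels whose Pearson correlation with the
   target has two-sided $p < 0.05$.  Run inside the fold, never on the
   full sample: selecting before the fold split leaks the test subject
   into training, and the test suite demonstrates the resulting optimism
   with a deliberately leaky variant.
2. **Standardization** — features *and* target are centered and scaled by
   the training fold's statistics; predictions are mapped back to the
   original accuracy scale.  Scaling the target makes the
   $\varepsilon$-insensitive tube ($\varepsilon = 0.1$) meaningful in
   target-SD units — on a raw accuracy scale with SD near 0.1 the default
   tube would swallow the entire sample.
3. **Linear $\varepsilon$-SVR** (libsvm via `e1071`).  The regularization
   default is the SVMlight convention $C = 1 / \overline{\|x_i\|^2}$.
   A dimension-blind fixed $C$ is miscalibrated in the voxels $\gg$
   subjects regime: with per-voxel standardization, $\|x_i\|^2$ grows with
   the number of selected voxels, and a fixed $C = 1$ leaves the fit
   essentially unregularized — in simulation it recovered less than half
   of the attainable correlation, while the scaled default tracks the
   attainable value.  Any fixed $C$ can still be set via `svr_cost`.
   Note that $C = 1$ applied to *raw-unit* mALFF features (SD $\approx$
   0.05) is arithmetically equivalent to $C \approx 0.002$ on standardized
   ones, i.e. the scaled default reproduces the regime a default-settings
   libsvm run on unscaled features operates in — the common configuration
   of published neuroimaging SVR pipelines.

Accuracy is summarized by Pearson $r$ and mean squared error between the
$n$ held-out predictions and the actual scores.  Significance comes from
permutation: the behavioral scores stay fixed, the row order of the feature
matrix is randomly permuted (subject-to-brain assignment broken while the
spatial covariance of features is preserved — per-voxel scrambling would
destroy it), and the entire LOOCV including per-fold selection is rerun,
1,000 times by default.  The $p$ value of $r$ is the fraction of permuted
datasets with $r$ strictly greater than observed; for MSE, strictly lower.
No $+1$ smoothing is applied, matching the plain ratio definition; a zero
count is reported as `<1/N`.

For interpretation, a final model (selection + SVR on all patients)
back-projects absolute primal weights onto voxels, normalized so the
maximum is 1; each cluster is summarized by the maximum normalized weight
among its selected voxels, and cluster-mean mALFF is additionally
correlated with the target post hoc.

## Behavioral scoring

The visual-search task shows 2 or 4 faces, the emotional target present in
half the trials, in 6 blocks of 40 trials.  A trial is correct when the
response matches target presence; only trials with reaction time strictly
below 3 s are analyzed.  Two readings of "accuracy" are possible when
trials are RT-excluded; the package divides correct responses by *included*
trials (the exclusion sentence removes those trials from all further
analysis), with `denominator = "all"` available.  Trials without a keypress
are excluded rather than counted as errors; this is a documented
convention, not a claim about the original task.  Group summaries report
mean ± sample SD (n − 1) and never run inferential statistics — the mixed
ANOVA on accuracies is deliberately out of scope.

## The synthetic cohort

Because no patient data are distributable, the package generates a cohort
with the statistical structure the analysis assumes:

* **Noise**: per-frame white Gaussian fields, spatially smoothed to
  `noise_fwhm_mm` (default 6 mm) and rescaled to unit voxel variance;
  temporally white.  This is the simplest model under which the
  cluster-correction null is well defined.
* **Signal**: inside each spherical ROI, a sum of 3 sinusoids at random
  frequencies drawn inside the 0.01-0.08 Hz band with random phases, with
  amplitude $A\,(1 + \gamma\,\mathrm{patient} + u_s)$ — baseline $A$
  (`base_band_amp`), signed group effect $\gamma$, and a subject latent
  $u_s \sim N(0, 0.25^2)$ shared across the coupling ROIs (independent per
  ROI elsewhere) that creates the across-subject variance the SVR must
  exploit.
* **Behavior**: fearful accuracy is
  $\mathrm{clip}_{[0,1]}(\mu_{\mathrm{group}} + \beta A u_s + e_s)$ with
  $\beta = 0.28$ and $e_s \sim N(0, 0.07^2)$, so the brain-driven and noise
  components each contribute SD 0.07 — a signal-to-noise ratio of 1, with
  the patient fearful mean 0.74 and SD 0.10 matching the cohort the design
  emulates.  Happy accuracy is brain-independent noise around its group
  means (0.89 / 0.94), mirroring the empirical finding that the
  fearful-defined mask does not predict happy accuracy.  Clipping affects
  well under 1% of patient fearful scores, the quantity the model
  predicts; control and happy scores sit nearer the ceiling (as real
  accuracies do) and may clip occasionally, so the control-group SD runs
  slightly above its nominal value.
* **Geometry**: default 24^3 grid of 3-mm voxels; the brain mask is the
  inscribed ellipsoid (curved boundary without shipping an atlas); three
  default ROIs stand in for the posterior-midline (raised in patients),
  occipital (lowered, behavior-coupled) and sensorimotor (lowered,
  uncoupled) clusters.  All ROI spheres must lie inside the mask.
* **Determinism**: identical configurations generate bit-identical
  cohorts.  Volume noise uses a package-internal mt19937-64/Box-Muller
  stream seeded per subject, identical across platforms; phenotypes and
  signal frequencies use R's RNG.

The generator makes no attempt at hemodynamics, physiological noise,
motion, slice timing, or template registration (inputs are assumed already
normalized); passing tests on this cohort demonstrates the statistical
machinery — calibration of the cluster null, honesty of the nested
cross-validation, recovery of planted coupling — not robustness to those
real-data effects.  The linear amplitude-behavior coupling is a test
harness assumption, not an empirical claim.

## Numerical choices and degenerate inputs

* Band bins: closed interval with a $10^{-9}$ Hz tolerance; an empty band
  (too-short series) is a configuration error naming the band/TR/N
  combination; bands at or above Nyquist are rejected.
* A voxel with identical values in both groups yields $t = 0$, $p = 1$
  (not NaN).  Rank-deficient designs abort, naming the collinear columns;
  rank-deficient *nuisance* matrices fall back to the pseudo-inverse with
  a warning.
* Zero-variance features are excluded from selection with a warning; a
  fold with no selected features predicts the training mean and is
  flagged.  An SVR whose training points all fall inside the
  $\varepsilon$ tube (no support vectors) returns the flat model.
* Monte Carlo thresholds error when $\alpha$ is below the $1/n$
  resolution of the iteration count.
* Cluster size gating is $\ge$; the motion and RT gates are strict $<$.

## Scale of the validation experiments

The test suite exercises the pipeline at desk scale, chosen so the whole
suite runs in tens of minutes on one core while leaving each check
statistically meaningful: oracle-equivalence checks use the full 230-frame
series length; family-wise error calibration uses 200 null cohorts of
61 subjects on the 24^3 grid with 30-frame series (3 band bins — enough
for the map chain, generated in seconds); coupling recovery uses 10
cohorts at the full 240-frame length with 99 permutations; permutation
level uses 100 reduced cohorts (12^3 grid, 10 patients).
`scripts/acceptance.R` runs one complete default-scale pipeline (240
frames, 61 subjects) with 199 permutations and reports its summary
quantities as JSON.

## Known limitations

* The permutation and Monte Carlo inferences are calibrated under the
  generator's assumptions (Gaussian smooth noise, exchangeable subjects);
  heavy-tailed or temporally structured real data can behave differently.
* Smoothness estimation assumes an approximately Gaussian autocorrelation;
  heavily non-Gaussian residual fields bias the cluster threshold, as they
  do in the classical AlphaSim workflow.
* The SVR weight map is interpretable as a multivariate pattern; per-voxel
  weights of correlated features are not individually meaningful effect
  sizes.
* LOOCV correlation at n = 28 carries substantial sampling noise
  (SD ≈ 0.1 even for a perfect model at true r ≈ 0.7); single-cohort r
  values should be read with that in mind.
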