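---
title: "Methods: seed-based connectivity and weight-change prediction in bariconn"
author: "bariconn authors"
output: rmarkdown::html_document
vignette: >
  %\VignetteIndexEntry{Methods: seed-based connectivity and weight-change prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The analysis problem

bariconn implements a longitudinal seed-based resting-state functional
connectivity (RSC) analysis for a two-group cohort scanned before (T0) and
about eight months after (T8) bariatric surgery: 30 lean control
participants and 14 participants with severe obesity, each contributing a
10-minute resting-state BOLD run per session (304 volumes at TR = 2 s, the
first five discarded, so 299 analysed volumes). The chain runs:

1. **Denoising** — outlier-volume censoring, nuisance regression and
   band-pass filtering in a single fit.
2. **Connectivity** — seed-to-voxel Pearson correlation maps, Fisher
   r-to-z transformed; scalar ROI features as unweighted ROI means of z.
3. **Group maps** — voxel-wise 2 × 2 (group × time) planned contrasts with
   cluster-forming threshold p < 0.001 and cluster-level FDR q < 0.05
   against a group-label permutation null; FDR-surviving baseline clusters
   become the obesity-sensitive ROIs (a ventral-striatum-like region where
   obese < lean, and a dorsolateral-prefrontal-like region where
   obese > lean).
4. **Prediction** — leave-one-participant-out (LOOCV) linear regression of
   weight change (kg, T8 − T0) on the scalar ROI connectivity feature,
   summarised as the Pearson correlation between predicted and observed
   change, with parametric and permutation inference.
5. **Hormones** — the leptin-per-kilogram-body-fat ratio
   `x = (leptin_T0 − leptin_T8) / (fat_T0 − fat_T8)` correlated with the
   connectivity change `y = z_T8 − z_T0` over the obese group.

Because the study's raw participant data are not deposited, the package
ships a first-class synthetic-cohort generator whose defaults encode the
study conditions, so every downstream stage can be validated against a
planted ground truth.

# The synthetic cohort generator

`CohortSpec()` holds all generator parameters; `generateCohort()` draws
phenotypes and `generateBoldRun()` draws one session's 4D image.

## What the defaults encode

* **Group sizes and acquisition**: 30 lean + 14 obese; 304 volumes, 5
  discarded, TR = 2 s. The grid is a 20 × 20 × 20 voxel volume at 3 mm
  spacing (diagonal affine) — a desk-scale stand-in for an MNI-resolution
  brain, roughly 27× fewer voxels. Masks (seed, two target ROIs, white
  matter, CSF) are disjoint axis-aligned boxes placed fractionally so the
  layout scales with the grid.
* **Planted coupling**: seed-to-ventral-striatum coupling is weaker in the
  obese group at baseline (target Pearson r 0.10 vs 0.30 lean) and rises
  after surgery (0.28); the prefrontal ROI is stronger in the obese group
  (0.35 vs 0.10) with *no* change over time, so its change feature is a
  true null for prediction — the dissociation the analysis is designed to
  expose. Between-participant coupling variation is 0.12 Fisher-z (trait)
  plus 0.05 per session; the obese coupling change varies with SD 0.10.
* **Weight model**: obese weight change is
  `−34 kg + β · (Δz − mean Δz) + ε`, with planted slope β = −30 kg per
  Fisher-z unit and ε of 5 kg; lean changes are N(0, 1.5 kg). The −34 kg
  offset matches the group-mean drop from 119 to 85 kg.
* **Hormones**: leptin follows body fat cross-sectionally
  (≈ 1.36 ng/ml per kg with intercept −14.1, hitting the lean 17 kg → 9
  ng/ml and obese 62 kg → 70 ng/ml group means) and longitudinally through
  an individual ratio of mean 2.25 ng/ml per kg fat lost (so group-mean
  leptin falls to ≈ 25 ng/ml as fat falls to ≈ 42 kg). The individual
  ratio is drawn jointly with the individual connectivity change at
  correlation 0.7. That value was set by an a-priori power analysis: with
  n = 14 and a chance bound of ≈ 0.46, a planted correlation of 0.7 is
  detected in ≈ 90% of cohorts, while the observed sample correlation in
  any one cohort can easily be in the 0.5–0.6 range.
* **BOLD structure**: seed voxels share a band-limited (0.01–0.1 Hz)
  latent course s; each target-ROI voxel is `r·s + sqrt(1−r²)·η` with
  independent band-limited η, so its expected correlation with the seed
  mean equals the planted r. White matter and CSF follow their own slow
  latent courses (0.002–0.02 Hz); all other voxels are white noise plus
  slow polynomial drift, on a baseline of 1000 with 1% signal amplitude.
  The latent signals live inside the analysis band deliberately, so
  denoising does not destroy the planted coupling.
* **Motion**: translations follow a slow random walk (per-step SD
  0.008 mm) with spikes at a per-volume rate of 0.01 (lean) and 3× that
  for the obese group, reflecting that the obese participants moved more;
  the study does not quantify the difference, so the multiplier is a
  package choice. Spike volumes also receive a global intensity
  disturbance so the intensity-based censoring criterion has something to
  find. Participant-level exclusion uses a peak-displacement summary with
  the 3.5 mm threshold; whether that study threshold refers to peak
  displacement or peak framewise displacement is unstated, and the package
  defaults to peak absolute displacement.

All randomness flows from one master seed; per-participant and
per-session streams are derived from the participant id, so any run can
be regenerated in isolation.

## What the generator does not emulate

No anatomy, k-space, slice-timing, field inhomogeneity, physiological
(cardiac/respiratory) signal, spatial autocorrelation of noise, or
registration error. Passing tests therefore show that the *statistical
machinery* behaves as specified under known ground truth — not that the
pipeline is robust to the full artefact spectrum of real fMRI.

# Denoising

`detectOutlierVolumes()` flags a volume when the z-score of the linearly
detrended volume-mean intensity exceeds 3, or the framewise displacement
(FD) is ≥ 0.5 mm. The analysis tool the study names does not publish its
exact formulas, so two conventions had to be fixed here:

* **FD** is the sum of absolute backward differences of the three
  translations plus 50 mm × the absolute rotation differences (arc length
  on a 50 mm sphere) — the dominant convention in the motion-scrubbing
  literature. The first volume has FD 0.
* **Global signal z** is the z-score of the linearly detrended
  volume-mean intensity series.

`buildNuisanceDesign()` assembles 18 motion-derived columns (6 rigid-body
parameters, first and second backward-difference derivatives, first rows
padded with 0), mean signals from eroded white-matter and CSF masks
(`erodeMask()`, 6-connected, one pass by default — the study says only
"further eroded"), linear and quadratic trends, and a one-hot indicator
per flagged volume.

`denoiseRun()` honours "regression and band-pass performed
simultaneously, only on surviving volumes" by a single least-squares fit
per voxel, over retained volumes only, against the design augmented with
a discrete cosine basis spanning all frequencies outside 0.01–0.1 Hz
(band-stop by regression). This is deterministic, makes residuals exactly
orthogonal to every nuisance regressor, and cannot re-introduce censored
volumes. Numerical choices: spike indicators become identically zero once
their volume is excluded and are dropped silently; any other
zero-variance column (e.g. derivatives of a still trace) is dropped with
a warning, ties broken by column order; the fit refuses to run with fewer
than K + 10 retained volumes. One consequence of the cosine band-stop is
worth knowing: a signal band-limited in the *Fourier* basis leaks
slightly into the stop band of the *cosine* basis at the series
boundaries, so "in-band signal is untouched" holds exactly in the
filter's own basis and approximately otherwise.

`smoothVolume()` implements separable Gaussian smoothing with
σ = FWHM / (2√(2 ln 2)) per axis in mm converted through the affine, with
kernel rows renormalised at the boundary (constants are preserved
exactly). The study smoothed at 8 mm FWHM at MNI resolution; on the
synthetic grid smoothing is off by default because the planted ROIs are
only one kernel-width wide.

# Connectivity

`seedMeanTimecourse()` is the unweighted mean over seed voxels;
`seedToVoxelMap()` correlates it with every voxel over retained volumes
and applies z = atanh(r). |r| is clipped at 1 − 10⁻⁶ first so that
degenerate voxels (e.g. inside the seed) stay finite; seed-internal
voxels are reported, not masked. Zero-variance voxels get z = 0 with a
warning. `roiMeanZ()` averages z over an ROI — the scalar feature used
downstream.

# Group-level inference

The 2 × 2 factorial analysis is realised as the planned contrasts the
study reports — obese vs lean at T0, at T8, and the interaction as an
unpaired contrast on within-participant change maps — rather than a full
mixed-effects engine. The study's cluster inference ran under parametric
random-field assumptions; this package replaces it with a nonparametric
group-label permutation null of the *maximum* supra-threshold cluster
extent (`nullMaxExtents()`, default 1000 permutations, fixed seed),
giving cluster p values with +1/(B+1) smoothing and Benjamini–Hochberg
FDR across clusters (`clusterFdr()`). The replacement is assumption-free,
desk-scale and directly testable; peak values are reported as t (the
study prints probit-converted peak Z-scores, a cosmetic difference).
Cluster connectivity defaults to 6 (faces); 18/26 are available.

ROI selection (`selectObesitySensitiveRois()`) uses only T0 maps, so no
information about T8 or weight change can leak into the ROI definition —
a property asserted by a dedicated test that shuffles the T8 maps and
observes identical ROIs.

For the hormone analysis the ventral-striatum ROI is taken from the
group × time interaction map (positive clusters at p < 0.001 passing an
extent threshold), mirroring the study's use of the interaction cluster
to rule out non-specific drift. The study's 50-voxel extent threshold is
an MNI-resolution figure; on the 20³ synthetic grid, where the planted
ROIs are 27 voxels, the config default is 10 voxels. All other
thresholds keep the study's printed values (z = 3, 0.5 mm, p < 0.001,
q < 0.05, 10 000 permutations).

# Prediction

`loocvPredict()` fits, for each participant i, ordinary least squares of
weight change on the scalar feature over the other n − 1 participants and
evaluates it at z_i. The study's printed prediction equation omits the
trained intercept while its model equation includes one; the package
applies the intercept by default (standard OLS prediction) with
`intercept = FALSE` reproducing the literal slope-only form. Whether the
study predicted from feature *levels* or *changes* is equally unstated;
both are supported (`featureType` in the pipeline config) and the default
is the change feature, because only the change feature can produce the
reported dissociation — baseline levels of *both* ROIs separate the
groups and would both "predict" the group-dominated weight change.

Agreement is summarised by Pearson r between predicted and observed
change, with a two-tailed parametric p from
t = r√(n−2)/√(1−r²), and a permutation chance interval (5th/95th
percentiles, matching the study's printed ±0.25 at n = 44 and ±0.46 at
n = 14, which equal the 5th/95th — not 2.5th/97.5th — percentiles of the
permutation null, about 1.65/√(n−1)).

**The permutation mode is the one place this package deliberately departs
from the simplest reading of the study's procedure.** Shuffling the
observed values against *fixed* LOOCV predictions produces a null
centred at zero, but the LOOCV predicted-vs-observed correlation itself
is negatively biased under the null: with no signal, each left-out
participant's prediction is driven by training-fold fluctuations that
anti-correlate with the left-out observation (simulated null mean ≈
−0.15 without the intercept and ≈ −0.32 with it, at n = 44). Compared
against a symmetric fixed-prediction interval, a truly null feature
therefore "escapes" far more often than 10%. The default mode `"full"`
re-runs the entire leave-one-out fit inside every permutation, so the
null distribution is that of the complete statistic and the interval is
exactly calibrated by exchangeability; mode `"fixed"` reproduces the
simpler convention. The plain two-vector `correlationInference()` (used
for the hormone correlation, where nothing is cross-validated) keeps the
simple shuffle.

# Hormone statistics

`leptinPerFatRatio()` computes x with a guard: participants whose
absolute fat change is below 0.01 kg have an undefined ratio and are set
to NA with a warning rather than producing huge values.
`hormoneConnectivityCorrelation()` delegates inference to
`correlationInference()`. `changeTests()` reports the paired (obese T0 vs
T8) and two-sample (lean vs obese at T0) t tests for weight, BMI, body
fat (kg, %) and leptin; paired tests on 14 participants have df = 13 as
in the study's printed statistics. Insulin and glycaemia are carried
through the phenotype table and the same correlation machinery can be
applied to them; the package asserts nothing about their effects.

# Problem sizes and reproducibility

The test-suite simulations are sized for a single desk CPU: calibration
checks use 100 replicates of 8³-voxel runs at full length (T = 299);
denoising contracts run once at the full 20³ × 299 size; parameter
recovery uses 100 cohorts of 44 with 1000-permutation inference; cluster
inference uses 100 null replicates at 12³ with 500 label permutations
and the baseline group sizes (40 vs 16). Monte-Carlo rate assertions are
stated net of their binomial standard error (e.g. a nominal 90%
containment rate over 100 replicates is asserted at ≥ 84%). Every
simulation derives from fixed seeds; the full pipeline writes a manifest
with a config hash and per-stage counts, and rerunning a config with the
same seed reproduces every output byte for byte.

# Known limitations

* Synthetic geometry is box-shaped and coarse; no claims about anatomical
  localisation or atlas labelling are possible.
* The factorial model is realised as planned two-sample contrasts; no
  covariate adjustment is implemented (none is reported in the study).
* The permutation cluster null permutes group labels, which is exact for
  the between-group contrasts but only approximate for designs with
  within-participant structure beyond the change-map reduction.
* Hormone modelling is statistical, not physiological: leptin dynamics
  are a linear function of fat with noise, adequate for testing the
  correlation machinery and nothing more.
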