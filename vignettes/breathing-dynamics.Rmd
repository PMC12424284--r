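---
title: "Quantifying breathing dynamics: models, estimators, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying breathing dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(breathdyn)
```

## The problem

A respiration belt samples chest-wall displacement (here at 10 Hz) while a
participant rests or performs a task. Block averages of breathing rate or
amplitude discard the temporal structure of the signal; `breathdyn`
characterizes that structure with a sixteen-feature *dynamics vector* —
eight metrics on each of the breath-by-breath rate and amplitude series —
and carries it through to group-level inference: a varimax PCA of the
feature space, paired rest-versus-task contrasts with FDR control, and
partial least squares correlation (PLSC) linking breathing dynamics to
anxiety scores or working-memory efficiency.

This vignette documents the models and estimators, the tunable parameters
and their defaults, the synthetic-cohort generator used for validation, and
the design decisions taken where the methodology left genuine choices.

## From belt signal to breath series

The raw signal is band-passed with a 2nd-order Butterworth filter applied
forward-backward (`signal::filtfilt`), pass band 0.05–3 Hz. Zero-phase
filtering matters because breath timing is the measurand: a causal filter
would delay extrema by a rate-dependent lag. The band brackets human
breathing (a 6 s breath is 0.17 Hz; the fastest plausible is well below
3 Hz) and removes both drift and sensor noise; the residual mean is
subtracted so the zero-crossing baseline is exactly zero.

Extrema come from the zero-crossing walk: between an upward and the next
downward crossing the maximum is an inhalation peak; between a downward and
the next upward crossing the minimum is an exhalation trough. The partial
segments before the first and after the last crossing also contribute an
extremum so edge breaths keep a full trough–peak pair. Two cleanups follow:

* **Ripple pruning.** Adjacent peak–trough pairs whose vertical distance is
  below `amp_min_frac` (default 0.3) times the median pair distance are
  removed and alternation re-enforced. The threshold is a fraction rather
  than an absolute value so it adapts to each recording's gain; 0.3 is a
  stand-in for the unspecified pruning rule of the zero-crossing method
  this step follows, and it is exposed as a parameter.
* **Sub-sample refinement.** Breath tops are flat, so the sample-grid
  argmax jitters under noise by several samples. Each extremum is refined
  by the vertex of a tricube-weighted quadratic fit over ±0.4 half-cycles;
  the window is kept deliberately narrow because unequal inhale/exhale
  durations make wider parabola fits lean toward the flatter side. Heights
  use an unweighted fit over the same window (harder noise averaging).
  On noise-free synthetic waveforms the refined peak times match the
  planted times to within one sample; on noisy cohorts the mean absolute
  rate error is ≈0.15–0.3 breaths/min and the per-breath amplitude
  correlation with ground truth exceeds 0.95.

The rate series is 60/(t<sub>i+1</sub> − t<sub>i</sub>) breaths/min for
consecutive peak times, assigned to the later peak; the amplitude series is
peak value minus immediately preceding trough value; both are aligned on
peaks 2..n. Recordings with fewer than 20 breaths are flagged and rejected
by `compute_dynamics()`.

## The eight metrics

All metrics operate on the breath-indexed series treated as unit-sampled —
no interpolation to clock time, so "frequency" means cycles per breath and
"lag" means breaths.

* **Mean, SD, CV.** SD uses the n−1 denominator; CV = SD/mean is the
  scale-free variability index.
* **ACW-50.** Biased (n-denominator) normalized autocorrelation; the
  timescale is the first integer lag with acf < 0.5, no interpolation.
  For an AR(1) with φ = 0.9 the closed form gives lag 7
  (0.9⁷ ≈ 0.478), which the estimator reproduces at large n. A censoring
  flag exists for series that never drop below 0.5 within n/2 lags,
  though with the biased demeaned estimator (whose lags sum to −1/2) the
  condition is effectively unreachable — the flag is defensive.
* **PSD slope.** Raw periodogram of the demeaned series over
  0 < f ≤ 0.5, OLS of log₁₀ power on log₁₀ frequency over all positive
  frequencies; the reported β is minus the regression slope, so β > 0
  means low-frequency dominance and a *decrease* in β is a shift toward
  faster frequencies. No frequency-band restriction is applied — an open
  choice; the unrestricted fit recovers planted β ∈ {0, 1, 2} within
  ±0.2 at n = 4096.
* **LZC.** The series is binarized at its mean (ties map to 1) and parsed
  with the exhaustive LZ76 production scheme; the phrase count c is
  normalized as c·log₂(n)/n, which approaches 1 for an incompressible
  sequence. Convention: the trailing phrase is counted only when it ends
  in an innovation, so a constant series has c = 1. The compiled parser
  matches a literal substring-search oracle on every binary string of
  length ≤ 12.
* **SampEn.** Template matching with m = 2, r = 0.2·SD, delay 1 —
  the classic convention, exposed as parameters because the methodology
  names them without fixing values. Self-matches are excluded; both
  template lengths use the same N − m·delay template set, so A/B is a
  conditional probability. When no (m+1)-template pair matches the value
  is undefined and returned as flagged `NaN` rather than an arbitrary
  number; downstream stages drop such entries (listwise for PCA/PLSC,
  pairwise for the paired tests). The implementation equals an O(n²)
  brute-force counter exactly, and for iid Gaussian input approaches
  −ln(erf(0.1)) ≈ 2.19.
* **MSE.** Coarse-grain by averaging non-overlapping windows of size τ,
  then SampEn at each scale with the tolerance *fixed* from the original
  series' SD (Costa convention; per-scale re-estimation is available via
  `rescale_r`). Scales default to 1..min(10, ⌊N/10⌋); scales whose coarse
  series is too short for SampEn contribute `NaN` and are excluded from
  the summary, which is the mean of finite per-scale values (an AUC
  option exists). At scale 1 MSE is identically SampEn.

Invariances, verified by tests: CV, LZC, SampEn and MSE are unchanged under
positive affine scaling of the input (binarization threshold and tolerance
move with the data); ACW-50 and the PSD slope are unchanged under positive
linear scaling.

## Table transforms

Inference runs on log-transformed features (to temper right skew); columns
containing any non-positive value — possible for the PSD slope — pass
through untransformed with a warning. Site harmonization is a
location/scale adjustment: each site's values are standardized by the site
mean/SD and rescaled to the pooled mean/SD, feature by feature, after
which every site mean equals the grand mean. This is the ComBat idea
without empirical-Bayes shrinkage; with the moderate feature count and
site sizes here the shrinkage adds machinery without changing the
conclusion, and the simpler adjustment is exactly invertible reasoning.
Transform states are tracked (`raw → logged → harmonized`) and enforced.

## Inference

**PCA.** Eigendecomposition of the feature *correlation* matrix (the
features have heterogeneous units), eigenvalue > 1 retention, varimax
rotation with Kaiser normalization, and a sign convention that makes each
component's dominant loading positive. Communalities are invariant under
the rotation (checked to 1e−8). Component scores are least-squares
projections of the z-scored data.

**Paired contrasts.** Two-sided paired t-tests on rest − task differences
(so a task increase yields negative t), Cohen's d = mean(diff)/SD(diff) —
hence d = t/√n exactly — and Benjamini–Hochberg adjustment across the 16
features. Undefined feature values drop pairwise; identical tables return
the null result (t = 0, p = 1) by convention.

**PLSC.** Both blocks are z-scored; R = X'Y/(n−1) is decomposed by SVD.
Effect size per latent variable is the cross-block covariance proportion
s²ᵢ/Σs²ⱼ. The permutation test shuffles rows of Y only and compares
singular values LV-by-LV without re-rotation — the simplest defensible
scheme — with the add-one p-value (1 + #{s\*ᵢ ≥ sᵢ})/(n_perm + 1); under
an independent null its LV1 rejection rate at α = 0.05 is nominal and the
p-values are uniform. The bootstrap resamples subjects jointly in X and Y,
aligns each replicate to the original axes by an orthogonal Procrustes
rotation of U (applied to V as well) to prevent sign/order flips, and
reports percentile 2.5/97.5 intervals; a salience is *reliable* when its
interval excludes zero. Percentile CIs are used rather than bootstrap
ratios because the downstream decision rule is stated in terms of CIs
crossing zero. Replicates that produce a constant column are redrawn and
counted.

**Efficiency.** Accuracy divided by mean reaction time per subject × load,
with RT taken over correct trials (the inverse-efficiency convention;
`rt_trials = "all"` is available since the choice is not dictated).
Fast/slow presentation speeds are pooled within load because the outcome
block is per-load efficiency.

**Anxiety Y-block.** PLSC against anxiety defaults to the 21 BAI items
rather than the total score: a single-column Y yields exactly one latent
variable, and a multi-LV anxiety structure requires the item-level block.
`y_block = "total"` is supported.

## The synthetic cohort: what it emulates, what it does not

The generator is the package's validation instrument — its defaults encode
the study design it emulates: a 5-minute resting state and an
approximately 30-minute task state at 10 Hz, 51 paired subjects (or larger
rest-only cohorts), BAI item scores, and 80 N-back trials per load.

Per-breath rates follow base + AR(1) + 1/f + white jitter, clipped to
4–60 breaths/min; peak times are planted so the interval ending at peak i
is exactly 60/rateᵢ, making the planted rate series recoverable without a
half-breath ambiguity. The waveform interpolates alternating trough/peak
extrema (−amplitudeᵢ/2, +amplitudeᵢ/2) with half-cosine segments and adds
white sensor noise (SD 0.05 against unit rest amplitude). Rest breathing
is slow-wandering and regular (φ ≈ 0.93, minimal jitter, no 1/f
component); task breathing is faster (17 vs 14 bpm), shallower (0.75 vs
1.0), more variable (rate SD ≈ 1.2 vs 0.6 bpm) and more irregular across
timescales (a substantial 1/f component plus white jitter). The 1/f
component matters: white irregularity alone averages away under
coarse-graining, so multiscale entropy would barely separate conditions —
task complexity must live at multiple timescales, which is also the
qualitative claim the contrast encodes. Rate-modulation depths (CV ≈ 4%
at rest, 7% at task) sit at the conservative end of the 5–20% range
reported for breath-interval variability, large enough that the ≈0.2
breaths/min extraction-noise floor of a 10 Hz belt does not mask the
planted structure.

Between-subject structure comes from two independent latents: a
*variability* scale (log-normal multiplier on all rate-modulation SDs)
that lowers working-memory efficiency (efficiency =
base_load · exp(−0.55·z) with trial-level realization), and an
*irregularity* latent that whitens resting breathing (smaller smoothness
φ, larger jitter) and drives the BAI latent (r = 0.65), discretized into
21 items through thresholds chosen for a subclinical score distribution.
Smoothness parameters also carry idiosyncratic per-subject jitter so
integer-valued features (ACW-50) vary across subjects. Site effects are
additive rate offsets and multiplicative amplitude scales.

The planted ground truth records, per cohort: every recording's peak
times, rates and amplitudes; the subject latents; the expected
rest-minus-task sign for the eight robustly shifted features (mean,
SD, ACW-50, PSD slope, LZC, SampEn and MSE of the rate series, and mean
amplitude); and the features expected to carry the efficiency coupling
(SD and CV of the task rate series). Validation requires paired tests to
recover all planted signs with BH-significant adjusted p, and the PLSC
bootstrap to flag SD/CV as the top reliable saliences, in ≥90% of
replicate cohorts.

What the generator does *not* emulate: inhale/exhale asymmetry (the
half-cosine primitive supports it, but it is not planted), apneas and
sighs, movement artifacts, non-stationary drift in task engagement, and
item-level BAI factor structure beyond a single latent. Passing tests
therefore demonstrate estimator correctness and pipeline sensitivity
under clean, stationary physiology — not robustness to the full
messiness of field recordings.

## Numerical choices and degenerate inputs

* SampEn/MSE undefined values propagate as `NaN` with warnings, never as
  silently substituted numbers; rows with undefined features are excluded
  listwise from PCA and PLSC (with a message) and pairwise from paired
  tests.
* Series length floors: SampEn needs 4(m+1) points, PSD 32, ACW 10, LZC
  16; `compute_dynamics` enforces ≥20 breaths and attaches the offending
  feature's name to any error.
* The LZC binarization maps values equal to the mean to 1, fixing the
  constant-series case (c = 1).
* Zero-variance checks use exact equality for raw series and a relative
  tolerance (1e−10 of the largest difference) for paired differences,
  where float cancellation can leave sub-epsilon residue.
* Rest and task series lengths differ (~75 vs ~500 breaths) and entropy
  estimators are length-biased — short regular series read *higher* in
  SampEn than their long counterparts would. The pipeline follows the
  full-series convention; recordings can be truncated to a common breath
  count upstream if a length-matched analysis is wanted. This bias is one
  reason the generator's rest/task irregularity contrast is planted
  generously.
* Every stochastic operation (generators, permutation, bootstrap) takes
  an explicit seed; pipeline commands write the seed and configuration
  into `manifest.json`.

## Problem sizes used in validation

The test suite validates estimators at the sizes where their oracles are
exact or their asymptotics are informative: brute-force SampEn equality at
n ≤ 200, exhaustive LZ76 up to length 12, closed-form ACW/SampEn/PSD
recoveries at n = 10⁴–10⁵, permutation calibration over 500 null
replicates of n = 100 with 200 permutations each, and 100 replicate
51-subject cohorts for the end-to-end recovery checks — the same cohort
size as the paired design it emulates, with the bootstrap at 500
replicates per fit inside that loop (1000 elsewhere).

## Known limitations

The detector assumes a single dominant breathing oscillation; severely
disordered breathing (Cheyne–Stokes-like envelopes, long apneas) would
need upstream segmentation. The PSD slope is fitted over all positive
frequencies of short breath-indexed series, so it mixes any oscillatory
peak into the power-law estimate. ACW-50 on integer lags is coarse for
short series. The permutation scheme tests LVs marginally, not the joint
null across LVs. And the harmonization removes site location/scale only —
site-by-feature interactions beyond that are out of scope.
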