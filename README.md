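# breathdyn

Breathing is not a constant rhythm: its rate and depth wander, and the
*structure* of that wandering — how variable, how irregular, how
long-memoried the breath-by-breath series is — carries information about
affective and cognitive state that a block-averaged breathing rate throws
away. `breathdyn` is an R package for psychophysiologists who record
respiration with a chest belt and want to quantify those dynamics and
relate them to behavioral outcomes such as anxiety questionnaires or
working-memory performance.

The package implements the full analysis chain:

1. **Preprocessing** — zero-phase Butterworth band-pass (0.05–3 Hz) of the
   belt signal, zero-crossing detection of inhalation peaks and exhalation
   troughs with pruning of sub-breath ripples, and extraction of the
   per-breath rate series (60/(t
   <sub>i+1</sub> − t<sub>i</sub>) breaths/min from successive peak times)
   and amplitude series (peak minus preceding trough).
2. **Dynamics features** — eight metrics on each series, sixteen features
   per recording:
   * central tendency: mean;
   * variability: SD and CV = SD/mean;
   * timescales: ACW-50 (first lag where the autocorrelation drops below
     0.5) and the spectral exponent β of the power law P(f) ∝ 1/f^β,
     fitted by OLS of log₁₀ power on log₁₀ frequency;
   * complexity/entropy: normalized Lempel–Ziv complexity
     c·log₂(n)/n from an exhaustive LZ76 parse of the mean-binarized
     series; sample entropy SampEn(m, r, N) = −ln(A/B) with m = 2,
     r = 0.2·SD, Chebyshev matching, self-matches excluded; and
     multiscale entropy (mean SampEn over coarse-grained scales with the
     tolerance fixed from the original series' SD).
3. **Table transforms** — natural-log transform of the feature table and
   location/scale site harmonization.
4. **Inference** — varimax-rotated PCA (eigenvalue > 1 retention on the
   correlation matrix); paired rest-vs-task t-tests with Cohen's
   d = mean(diff)/SD(diff) and Benjamini–Hochberg FDR control; and
   partial least squares correlation (PLSC): SVD of the z-scored
   cross-block correlation matrix, cross-block covariance proportions
   s²ᵢ/Σs²ⱼ per latent variable, permutation p-values (Y rows shuffled,
   add-one rule), and bootstrap percentile CIs on the saliences with
   Procrustes alignment; a salience is *reliable* when its 95% CI
   excludes zero. Working-memory efficiency is accuracy / mean RT per
   subject and N-back load.
5. **Synthetic cohorts** — a ground-truthed generator of belt-like
   waveforms (half-cosine lobes through planted trough/peak extrema,
   AR(1) + 1/f + white rate modulation, additive sensor noise), BAI item
   scores coupled to a breathing-irregularity latent, and N-back trials
   whose efficiency is negatively coupled to a breathing-variability
   latent. Every stage of the pipeline is validated against these
   planted values.

## Worked example

```r
library(breathdyn)

# simulate one resting-state belt recording (5 min at 10 Hz)
params <- cohort_spec(seed = 7)$rest
sim <- gen_breathing_signal(params, seed = 7, subject_id = "demo")

# raw signal -> breath-by-breath series -> 16 dynamics features
filtered <- bandpass_filter(sim$recording, low = 0.05, high = 3)
events <- detect_breath_extrema(filtered, fs = 10)
series <- extract_breath_series(filtered, events, fs = 10)
series
#> <breath_series> 76 breaths, rate 13.6-17.8 bpm
round(compute_dynamics(series), 3)
#>      mean_rate       mean_amp        sd_rate         sd_amp        cv_rate
#>         15.419          0.968          0.998          0.082          0.065
#>         cv_amp     acw50_rate      acw50_amp psd_slope_rate  psd_slope_amp
#>          0.085          4.000          3.000          1.700          1.212
#>       lzc_rate        lzc_amp    sampen_rate     sampen_amp       mse_rate
#>          0.658          0.987          1.792          1.674          1.579
#>        mse_amp
#>          1.674
```

The 76 detected breaths average 15.4 breaths/min with an SD of 1.0
breaths/min (CV 6.5%). The autocorrelation of the rate series stays above
0.5 for 4 breaths and its spectrum falls off as roughly 1/f^1.7 — slow,
structured wandering — while the entropy values (SampEn 1.79) sit well
below the ≈2.2 of an uncorrelated series of this tolerance, as expected
for regular resting breathing.

For a cohort, `gen_cohort()` produces paired rest/task recordings plus
anxiety and behavioral tables; `cohort_features()` stacks the per-recording
features; `log_transform_features()`, `harmonize_sites()`,
`pca_varimax()`, `paired_compare()`, `plsc_fit()` /
`plsc_permutation()` / `plsc_bootstrap()` run the statistics. The same
chain is scriptable from a shell via `inst/exec/breathdyn`
(`simulate`, `extract`, `pca`, `compare`, `plsc` subcommands).

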