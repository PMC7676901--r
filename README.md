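# eegretain

EEG correlates of learning from speech in noise: feature extraction,
component analysis, and retention modelling — with a fully synthetic,
ground-truthed cohort generator for validation.

## The problem

Listeners retain less of a spoken lecture when it is presented in
environmental noise (multi-talker babble, highway noise, fluctuating
traffic), and how much less varies across people and brain states. A
standard way to study this links per-channel EEG features recorded during
listening to a later information-retention exam. `eegretain` implements
that analysis chain end to end for researchers in auditory cognition and
EEG biostatistics:

1. **Synthetic cohorts** (`simulate_cohort`, `generate_recording`) —
   multichannel EEG with a 1/f<sup>β</sup> background, region-weighted
   alpha oscillators whose amplitude envelopes are fractional Gaussian
   noise with planted Hurst exponent *H*, condition/participant effect
   plans, a delayed sound-sync channel, and exam tables generated from the
   planted latents. Everything downstream can be validated by parameter
   recovery.
2. **Preprocessing** (`rereference`, `resample_filter`, `estimate_delay`,
   `split_fragments`) — nose re-referencing, anti-aliased resampling,
   zero-phase Hamming-sinc band-pass (order 3380, 0.5–134 Hz at 512 Hz),
   cross-correlation audio synchronization, fragment splitting; EDF
   read/write.
3. **Features** (`welch_psd`, `band_powers`, `spectral_shape`,
   `rootmusic_peak`, `fit_iaf`, `alpha_envelope`, `dfa`) — absolute and
   relative band powers AP/RP and the θ/α ratio; spectral center of
   gravity, bandwidth and 95% spectral edge per band; the alpha peak
   (MF, MP) by root-MUSIC subspace estimation (P = 2); the individual
   alpha frequency by a 1/f-detrended Gaussian fit with a
   prediction-bound acceptance test; and the alpha-envelope scaling
   exponents SEV1/SEV2 from detrended fluctuation analysis
   (fit interval 5–18 s), where 0.5 < SEV < 1 indicates long-range
   temporal correlations.
4. **PCA** (`build_matrix`, `fit_pca`, `subregion_scores`) — log-transform
   of power features, z-scoring, SVD decomposition **X** = **USV**ᵀ with
   scores **XV**, explained variance s²ᵢ/Σs², per-feature contributions,
   and scores averaged over six scalp subregions.
5. **Models** (`fit_lmm`, `tukey_posthoc`, `within_condition_models`,
   `exam_zscores`, `predict_exam`, `stepwise_backward`,
   `compare_models`) — mixed models of component scores
   (`score ~ task + subregion + (1|participant)` per background, and the
   task/background transpose), Tukey post-hoc tables, exam z-scores
   referenced to the silence condition
   (z = (keywords − μ_pink)/σ_pink per topic), and exam prediction with
   constant / background-type / full-EEG / backward-AIC-stepwise model
   families compared by AIC and likelihood-ratio χ² tests.

## Worked example

Simulate a small lecture-only cohort in which noisier backgrounds lower
the alpha-envelope Hurst exponent and exam scores carry a negative weight
on that latent, then run the pipeline:

```r
library(eegretain)

spec <- cohort_spec(n_participants = 8, tasks = "LA", fs = 256, n_channels = 6,
                    fragment_duration_s = c(LA = 45), topics_per_background = 1,
                    seed = 42)
osc <- oscillator_spec(center_hz = 10, peak_power = 4, bandwidth_hz = 2,
                       envelope_hurst = 0.72)
plan <- effect_plan(
  fixed_shifts = data.frame(task = "LA", background = c("MT", "HW", "FT"),
                            parameter = "envelope_hurst",
                            shift = c(-0.15, -0.08, -0.04)),
  exam_weights = c(envelope_hurst = -3))
cohort <- simulate_cohort(spec, osc, plan)
#> <eeg_cohort> 8 participants, 32 fragments, 6 channels @ 256 Hz

registry <- feature_registry(include = c("AP_alpha", "AP_theta", "RP_alpha",
                                         "RPTA", "CF_alpha", "SEV1", "SEV2"))
features <- cohort_features(cohort, registry, nfft = 2048)
pca <- fit_pca(build_matrix(features, registry))
pca
#> <eeg_pca> 192 observations x 7 features
#> cumulative explained variance: 41.8% 70.5% 91% 98.5% 99.7% 99.9% 100%
round(lrtc_contribution(pca), 1)
#>  PC1  PC2  PC3  PC4  PC5  PC6  PC7
#>  2.3 92.5  3.3  1.7  1.2 98.1  0.9

examz <- exam_zscores(generate_exam_table(cohort))
scores <- subregion_scores(pca, subregion_map(scalp_labels(6)), k = 3)
predict_exam(examz, scores, mode = "fixed", k = 3)
#> <exam_prediction> mode fixed, 32 rows
#>     constant   background     eeg_full eeg_stepwise
#>       176.84       179.04       176.56       159.81
#> stepwise retained: PC2_central, PC1_left_temporal, PC3_left_temporal,
#>   PC2_parietal, PC1_right_temporal, PC2_right_temporal, PC3_right_temporal
```

Reading the output: PC2 is the component dominated by the scaling-exponent
features (92.5% of its contributions come from SEV1/SEV2), and the
stepwise exam model keeps PC2 terms and beats the background-type model by
about 19 AIC points — the EEG components predict retention better than
knowing the noise type alone, and the planted negative LRTC→exam link is
recovered through the full chain. With only 8 participants the constant
model already beats `background`; background effects on the exam need the
larger cohorts used in the recovery studies.

A command-line pipeline wrapper (simulate → extract → pca → model, with a
YAML config and one seed) lives at `inst/cli/pipeline.R`:

```sh
Rscript inst/cli/pipeline.R run-all --out run1 --seed 7
```

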