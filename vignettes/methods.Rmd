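---
title: "EEG features, component scores and exam prediction: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{EEG features, component scores and exam prediction: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eegretain)
```

## The scientific problem

When people learn from spoken lectures presented in environmental noise
(multi-talker babble, highway noise, fluctuating traffic), how much of the
lecture they retain varies with both the listening condition and the
listener's brain state. `eegretain` implements a complete analysis chain for
studying this question with multichannel EEG: per-channel spectral and
temporal features are extracted from each listening fragment, compressed
into principal-component scores, and related to listening conditions and to
information-retention ("exam") z-scores with linear mixed-effect models.

Because raw cohort EEG of this kind is rarely shareable, the package ships a
synthetic-cohort generator with fully known ground truth. Every estimator in
the chain can therefore be validated by parameter recovery: plant a value,
run the pipeline, and check that the estimate comes back.

## The synthetic signal model

Each channel is the sum of two parts.

* **Scale-free background.** Gaussian noise with power spectrum
  $P(f) \propto f^{-\beta}$, synthesized in the frequency domain.
  $\beta = 0$ is white noise; EEG-like backgrounds use $\beta \approx 1$.
* **Oscillators.** Each oscillator is a narrowband carrier multiplied by a
  strictly positive amplitude envelope. The envelope is
  $1 + d \cdot \mathrm{fGn}_H(t)$ (floored at 0.05), where
  $\mathrm{fGn}_H$ is exact fractional Gaussian noise from circulant
  embedding and $d$ is the modulation depth (default 0.4). The Hurst
  exponent $H$ of the envelope is the planted ground truth for the
  long-range temporal correlation (LRTC) analysis.

The carrier is the *phase-normalized* analytic signal of band-pass-filtered
white noise: $\cos(\phi(t))$ with $\phi$ the instantaneous phase of the
filtered noise. A raw narrowband-noise carrier would contribute its own
Rayleigh-distributed envelope with short-range fluctuations that alias into
the fluctuation analysis and bias Hurst recovery well beyond the tolerance
this package holds itself to; the phase-normalized carrier keeps the
spectral bump of the requested bandwidth while making the planted envelope
*exactly* the Hilbert amplitude envelope of the component. This is a
deliberate design decision of the generator.

Oscillators are shared sources projected to channels through per-subregion
gains (no volume-conduction modelling): the downstream inference only ever
uses six scalp subregions, so a six-gain topography is the right level of
detail. Condition effects, participant effects and exam scores are planted
through an `effect_plan()`: additive shifts on the generator parameters
(alpha log-power, alpha center frequency, envelope Hurst, background
exponent) per condition cell, Gaussian per-participant intercepts, and exam
scores that are a rounded, clipped linear function of the z-scored planted
latents plus participant intercept and noise. Inter-participant variability
is Gaussian throughout — a modelling choice, since distributions of
individual differences are not otherwise constrained.

All randomness flows from one cohort seed; each fragment draws a derived
substream, so any fragment can be regenerated independently and
bit-identically (`realize_fragment()`).

What the generator does *not* emulate: acoustically realistic speech,
event-locked responses, eye or muscle artifacts, non-stationary drift, or
volume conduction. Passing recovery tests on this cohort therefore
demonstrates estimator correctness under the stated signal model, not
robustness to every property of real recordings.

## Preprocessing

Deterministic steps only: re-referencing to a named channel, anti-aliased
integer-ratio resampling, and a zero-phase Hamming-windowed-sinc FIR
band-pass (default order 3380 at 512 Hz, 0.5–134 Hz; pass-band ripple below
1 dB between 1 and 100 Hz). The filter is linear-phase and applied in a
single pass with the group delay compensated, so envelope timing — which
the fluctuation analysis depends on — is not distorted. Audio–EEG
synchronization estimates the lag of the recorded sound channel against the
presented audio by FFT cross-correlation; positive lag means the audio
arrives later in the recording, and ties break toward the smallest |lag|.

Artifact handling is intentionally out of scope: eye-artifact ICA and
visual rejection are judgment-based manual steps, so the pipeline instead
accepts explicit channel/interval exclusion lists (`read_exclusions()`).

## Feature extraction

**Welch spectra.** 1 s Hamming windows, 0.5 s overlap, zero-padded to
$2^{14}$ points by default; one-sided densities scaled so the
rectangle-rule integral equals the signal variance. Band integrals use
half-open bins $[f_{lo}, f_{hi})$, so the relative powers of bands that
partition 1–45 Hz sum to exactly 1. Features: absolute and relative band
powers for delta (1–4), theta (4–8), alpha (8–13 and 7–13), lower/upper
alpha, beta (13–30), gamma (30–45) and the wide band (1–45 Hz); the
theta/alpha ratio; and per band the spectral center of gravity CF, the
bandwidth B (root second central spectral moment — the conventional
"spectral spread"), and the 95% spectral edge frequency.

**Alpha peak by root-MUSIC.** The signal is band-passed (order-2
Butterworth, 7–13 or 8–13 Hz), its 64-lag autocorrelation matrix is
eigendecomposed, and the noise-subspace polynomial is rooted; the in-band
root closest to the unit circle gives the peak frequency, with the power
recovered from the signal-subspace eigenvalues. The 64-lag default is also
a numerical ceiling: the noise polynomial has degree $2(M-1)$ and root
finding becomes fragile beyond degree ≈ 130. With $P = 2$ the method
models a single real spectral *line*; peaks with substantial width are
estimated with a realization-dependent bias that grows with bandwidth,
which is why the recovery study plants near-line bumps (0.3 Hz).

**Individual alpha frequency.** A line is fitted to $\ln p(f)$ over
1–45 Hz to capture the $1/f$ background $z(f)$; a single Gaussian
$a_1 e^{-((f-b_1)/c_1)^2}$ is fitted to the detrended spectrum $p - z$
(initialized at the largest detrended alpha maximum, $b_1$ bounded to
7–14 Hz, $c_1$ to 0.05–5 Hz). The peak is accepted when its total height
$a_1 + z(b_1)$ exceeds the upper 95% prediction bound of the background fit
at $b_1$, evaluated on the linear-power scale — this makes the decision
invariant to rescaling the PSD, which a mixed ln/linear rule would not be.
The individual alpha interval is $[f_1, f_2]$ with $f_1$ the transition
frequency (minimum-power frequency between 4 Hz and the peak; the lower
bound 4 Hz is a configurable package choice) and
$f_2 = |5 - (f_\alpha - 1)| + f_\alpha$; the IAF is the center of gravity
$\sum f\,p / \sum p$ over that interval, with $f_2$ updated once from the
first pass and the center of gravity recomputed exactly once. The centroid
is computed on the raw PSD, as the defining formula states; note that a
non-negligible background inside $[f_1, f_2]$ then pulls the centroid away
from the bump center, so IAF and the Gaussian center $b_1$ agree only when
the peak dominates its interval.

**LRTC by detrended fluctuation analysis.** The alpha-band (8–13 Hz)
signal is extracted with a 0.25 s-order Hamming FIR filter (two cycles of
8 Hz; rounded up to an even tap count so the group delay is integral), the
amplitude envelope is the magnitude of the analytic signal, and DFA is
applied to the mean-centered cumulative sum: windows equally spaced on a
log scale (20 per decade by default) with 50% overlap, all placements
starting at the first sample and a trailing remainder discarded; each
window is linearly detrended by least squares; the fluctuation function is
the mean window standard deviation; and the scaling exponent (SEV) is the
log–log regression slope inside the 5–18 s fit interval, where the band
filter's influence is negligible. Two calculation ranges are retained
(SEV1: 2.5–180 s, SEV2: 0.1–180 s), with the upper bound capped at the
fragment length. An exponent strictly between 0.5 and 1 flags strong LRTC.

The windowed detrending is evaluated in closed form from prefix sums of
the profile, its time-weighted version and its square — algebraically
identical to per-window regression (the test suite checks agreement with a
direct windowed-regression implementation to 1e-10) but linear-time, which
is what makes 20-cohort end-to-end recovery studies affordable. The
cancellation error of the closed form stays benign because a DFA profile's
within-window excursions are on the same scale as its window means.

## PCA and subregion scores

Power-type features (absolute and peak powers) are natural-log
transformed; every column is z-scored with the sample SD ($n-1$ — the
convention is recorded in the matrix object). The SVD $X = USV^\top$
gives loadings $V$, scores $XV = US$, explained variance
$s_i^2/\sum s^2$, and per-component feature contributions — squared
feature–score correlations normalized to 100% per component. Component
signs are fixed by making each loading vector's largest-magnitude element
positive. PCA is fitted once on the pooled matrix across all conditions.
Channel-level scores averaged within the six scalp subregions (frontal,
central, left/right temporal, parietal, occipital — assigned from 10-20
label prefixes, overridable) feed the exam models; averaging happens on
raw scores after scoring, never re-normalized.

## Statistical models

Component scores are modelled per background (score ~ task + subregion +
(1 | participant)) and per task (score ~ background + subregion +
(1 | participant)); Tukey post-hoc tables with single-step family-wise
adjustment come from general linear hypotheses on the fitted models, with
marginal means computed on a balanced grid of the other fixed factors.

Exam z-scores standardize each topic's keyword counts by the mean and SD
of that topic's scores in the silence (pink-noise) condition across
participants. Exam prediction compares a constant model, a
background-type model, the full model with all $k \times 6$
subregion-averaged component scores, and a backward-AIC reduction of the
full model, in fixed (`lm`) and mixed (participant random intercept)
variants. All fits that enter AIC or likelihood-ratio comparisons use
maximum likelihood, not REML (REML likelihoods are not comparable across
fixed-effect structures); REML remains available for final coefficient
reporting. The mixed-model parameter count includes fixed coefficients,
variance components and the residual variance, so
$\mathrm{AIC} = -2\ell + 2\,\mathrm{edf}$ holds exactly. Backward
elimination drops, at each step, the single term whose removal lowers AIC
the most, and stops when no removal lowers AIC; it is deterministic given
the data, treats the subregion-averaged scores as atomic terms (no
interactions), and agrees with `stats::step(direction = "backward")` on
fixed-effect models. Nested ML fits are compared by the likelihood-ratio
chi-squared test; non-nested pairs report only the AIC difference. Exam
rows enter the prediction per topic (not averaged per background) — the
finer grain is the default and configurable upstream.

## Recovery studies and their problem sizes

The package validates itself with five recovery studies (exported as
`recover_*` functions; `scripts/acceptance.R` reruns them end to end).
The problem sizes are deliberate package choices balancing statistical
resolution against a single-CPU run of a few minutes:

* **DFA** (`recover_dfa`): planted envelope Hurst exponents 0.5–0.85,
  180 s at 512 Hz, 20 replicates each, fit 5–18 s. At this fragment
  length the DFA exponent's intrinsic sampling SD is ≈ 0.06–0.08 (there
  are only ~10–35 windows per fit-range size in 180 s), so
  across-replicate SDs below 0.05 are not generally attainable — a
  property of the estimator at this data length, consistent with the
  common guidance that stable DFA exponents need on the order of ten
  minutes of signal. Bias, by contrast, stays within ±0.03.
* **Alpha peak** (`recover_alpha`): bumps planted at 8.5, 10.0, 10.4 and
  12.0 Hz, 60 s at 256 Hz, bump width 0.3 Hz at ~6x background power —
  near-line bumps because the $P = 2$ subspace model is a line model (see
  above). Root-MUSIC and IAF errors are ≈ 0.02–0.04 Hz; the two
  estimators agree within 0.05 Hz.
* **Mixed models** (`recover_lmm`): 23 participants x 30 observations,
  planted task effect 0.5 with participant SD 0.3 and residual SD 0.5;
  Wald 95% CI coverage and null-calibrated Tukey error.
* **End-to-end exam prediction** (`recover_exam_prediction`): 16
  participants, lecture task only, 8 topics rotated so every topic is
  heard in silence by at least two participants, 45 s fragments at
  256 Hz, 6 channels (one per subregion), and a feature registry without
  the alpha-peak estimators (validated separately) and without SEF95
  (grid-quantized, hence near-constant, on short synthetic fragments).
  Planted structure: envelope Hurst lowered by the noisier backgrounds
  (−0.15, −0.08, −0.04), alpha power raised (+0.4, +0.25, +0.1),
  participant/fragment jitter of 0.05, and exam scores with weight −3 on
  the z-scored planted Hurst latent plus unit participant and residual
  noise. The study checks that backward selection keeps a term of the
  SEV-dominated component with a negative coefficient and that the
  stepwise model out-predicts the background-only model by AIC.
* **Synchronization** (`recover_delay`): exact delay recovery for a clean
  sound channel, and recovery of a 137-sample delay at 0 dB SNR.

## Numerical choices, degenerate inputs, limitations

Tolerances and tie-breaks that matter: cross-correlation ties break toward
the smallest |lag|; constant inputs (envelopes, correlation inputs,
feature columns) raise errors rather than returning NaN; a singular mixed
fit (variance component at zero) is retained and flagged, not refitted;
root-MUSIC with no in-band root projects the nearest root onto the band
edge and flags the result; IAF returns `accepted = FALSE` when no alpha
local maximum exists or the Gaussian fit fails. The Welch default of
$2^{14}$ FFT points at 512 Hz gives a 0.03125 Hz grid; simulation studies
may use coarser grids, recorded in each run's metadata. EDF export writes
16-bit samples with per-channel physical scaling (quantization ≈ range /
65535).

Known limitations: the topographic map is a thin rendering utility on
approximate 2-D positions, not analysis; the generator's envelope floor
(0.05) makes extreme modulation depths slightly sub-Gaussian; acceptance
behavior of the IAF peak test near its threshold depends on the
prediction-bound construction, which is specified here (linear-scale
background prediction interval) but not uniquely fixed by common practice;
and no claim is made about artifact-contaminated real recordings, which
must be cleaned (exclusion lists) before entering the pipeline.
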