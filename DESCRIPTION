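Package: eegretain
Title: EEG Spectral, Alpha-Peak and Long-Range Temporal Correlation
    Features for Modelling Learning from Speech in Noise
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying electrophysiological correlates of
    information retention while listening to speech in environmental
    noise. Provides a synthetic multichannel EEG cohort generator with
    planted ground truth (1/f background, region-weighted alpha
    oscillations with fractional-Gaussian-noise amplitude envelopes,
    condition and participant effects, exam scores driven by latent
    features); deterministic preprocessing (re-referencing, resampling,
    zero-phase FIR band-pass, audio synchronization by
    cross-correlation, fragment splitting); Welch power spectra and
    band-power, spectral-shape and spectral-edge features; alpha peak
    estimation by root-MUSIC and individual alpha frequency by a
    1/f-detrended Gaussian fit; detrended fluctuation analysis of the
    alpha amplitude envelope; SVD-based principal component analysis of
    z-scored feature tables; and linear mixed-effect modelling of
    component scores and exam z-scores with Tukey post-hoc comparisons,
    backward-AIC stepwise selection and likelihood-ratio model
    comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    minpack.lm,
    multcomp,
    signal,
    stats,
    tools,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
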