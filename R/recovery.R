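#' Hurst-exponent recovery study for the DFA estimator
#'
#' Generates offset-fGn amplitude envelopes (the simulator's envelope
#' model) with planted Hurst exponents and measures how well the DFA
#' scaling exponent recovers them with the standard 5-18 s fit interval.
#'
#' @param h_values Planted Hurst exponents.
#' @param n_seeds Monte-Carlo replicates per value.
#' @param duration_s Envelope duration (s).
#' @param fs Sampling rate (Hz).
#' @param envelope_depth Modulation depth of the offset envelope.
#' @param seed Master seed.
#' @return Data frame per planted value: `H`, `mean_sev`, `bias`,
#'   `mean_abs_err`, `sd_sev`, `n_seeds`.
#' @export
recover_dfa <- function(h_values = c(0.5, 0.55, 0.65, 0.75, 0.85),
                        n_seeds = 20, duration_s = 180, fs = 512,
                        envelope_depth = 0.4, seed = 1) {
  set.seed(seed)
  n <- round(duration_s * fs)
  rows <- lapply(h_values, function(H) {
    sev <- replicate(n_seeds, {
      env <- pmax(1 + envelope_depth * fgn_sim(n, H), 0.05)
      dfa(env, fs)$sev
    })
    data.frame(H = H, mean_sev = mean(sev), bias = mean(sev) - H,
               mean_abs_err = mean(abs(sev - H)), sd_sev = sd(sev),
               n_seeds = n_seeds)
  })
  do.call(rbind, rows)
}

#' DFA reference exponents for white and integrated noise
#'
#' @param n_seeds Replicates.
#' @param duration_s,fs Signal size.
#' @param seed Master seed.
#' @return Named numeric: mean exponent for a white-noise envelope
#'   (theory 0.5) and for integrated white noise (theory 1.5).
#' @export
dfa_reference_exponents <- function(n_seeds = 10, duration_s = 180, fs = 512,
                                    seed = 1) {
  set.seed(seed)
  n <- round(duration_s * fs)
  white <- mean(replicate(n_seeds, dfa(rnorm(n), fs)$sev))
  walk <- mean(replicate(n_seeds, dfa(cumsum(rnorm(n)), fs)$sev))
  c(white = white, integrated = walk)
}

#' Alpha-peak recovery study: root-MUSIC and IAF
#'
#' Plants a single strong narrow spectral bump on a pink background and
#' measures recovery of its center by the root-MUSIC peak frequency
#' (8-13 Hz band) and the fitted individual alpha frequency, plus their
#' mutual agreement.
#'
#' @param centers Planted bump centers (Hz).
#' @param n_seeds Replicates per center.
#' @param duration_s,fs Recording size per replicate.
#' @param peak_power,bandwidth_hz Bump strength and width (narrow strong
#'   bumps isolate estimator error from background skew).
#' @param seed Master seed.
#' @return Data frame per center: `center`, `mf_mae`, `iaf_mae`,
#'   `mean_abs_iaf_minus_mf`, `n_accepted`, `n_seeds`.
#' @export
recover_alpha <- function(centers = c(8.5, 10.0, 10.4, 12.0), n_seeds = 20,
                          duration_s = 60, fs = 256, peak_power = 6,
                          bandwidth_hz = 0.3, seed = 1) {
  set.seed(seed)
  rows <- lapply(centers, function(ctr) {
    res <- replicate(n_seeds, {
      osc <- oscillator_spec(ctr, peak_power = peak_power,
                             bandwidth_hz = bandwidth_hz,
                             envelope_hurst = 0.7)
      g <- generate_recording(duration_s, fs, n_channels = 1,
                              oscillators = osc, onef_exponent = 1,
                              keep_envelopes = FALSE)
      x <- g$recording$data[1, ]
      mf <- rootmusic_peak(x, fs, band = c(8, 13))$MF
      ia <- fit_iaf(psd_fine(x, fs))
      c(mf = mf, iaf = if (isTRUE(ia$accepted)) ia$IAF else NA_real_)
    })
    mf <- res["mf", ]
    iaf <- res["iaf", ]
    ok <- !is.na(iaf)
    data.frame(
      center = ctr,
      mf_mae = mean(abs(mf - ctr)),
      iaf_mae = mean(abs(iaf[ok] - ctr)),
      mean_abs_iaf_minus_mf = mean(abs(iaf[ok] - mf[ok])),
      n_accepted = sum(ok), n_seeds = n_seeds
    )
  })
  do.call(rbind, rows)
}

#' Mixed-model fixed-effect recovery and Tukey type-I error
#'
#' Two simulations mirroring the score-modelling stage. Recovery:
#' responses `y = 1 + 0.5 * I(task = LA) + u_participant + noise` with
#' `u ~ N(0, 0.3^2)`, `noise ~ N(0, 0.5^2)`; the fit's 95% Wald CIs must
#' cover both true fixed effects. Null: three identical task groups;
#' the family-wise-adjusted Tukey comparisons should rarely reach 0.05.
#'
#' @param n_seeds Replicates.
#' @param n_participants Participants per replicate.
#' @param n_obs Observations per participant.
#' @param seed Master seed.
#' @return List: `coverage` (seeds where both CIs covered truth),
#'   `n_seeds`, `type1_rate` (fraction of significant null pairs),
#'   `n_pairs`.
#' @export
recover_lmm <- function(n_seeds = 20, n_participants = 23, n_obs = 30,
                        seed = 1) {
  set.seed(seed)
  tasks <- c("BA", "BUA", "LA")
  make_data <- function(beta_la) {
    pid <- rep(sprintf("P%02d", seq_len(n_participants)), each = n_obs)
    task <- rep_len(tasks, n_participants * n_obs)
    u <- rnorm(n_participants, sd = 0.3)
    names(u) <- unique(pid)
    y <- 1 + beta_la * (task == "LA") + u[pid] + rnorm(length(pid), sd = 0.5)
    data.frame(participant = pid, task = task, y = y)
  }
  covered <- logical(n_seeds)
  for (i in seq_len(n_seeds)) {
    dat <- make_data(0.5)
    fit <- fit_lmm(y ~ task + (1 | participant), dat)
    co <- fit$coefficients
    ci_ok <- function(term, truth) {
      r <- co[co$term == term, ]
      truth >= r$estimate - 1.96 * r$se && truth <= r$estimate + 1.96 * r$se
    }
    covered[i] <- ci_ok("(Intercept)", 1) && ci_ok("taskLA", 0.5)
  }
  sig <- 0
  npair <- 0
  for (i in seq_len(n_seeds)) {
    dat <- make_data(0)
    fit <- fit_lmm(y ~ task + (1 | participant), dat)
    tk <- tukey_posthoc(fit, "task", dat)
    sig <- sig + sum(tk$comparisons$p_adj < 0.05)
    npair <- npair + nrow(tk$comparisons)
  }
  list(coverage = sum(covered), n_seeds = n_seeds,
       type1_rate = sig / npair, n_pairs = npair)
}

#' End-to-end exam-prediction sign-recovery study
#'
#' Simulates a lecture-only cohort whose exam scores carry a negative
#' weight on the planted envelope-Hurst latent, runs the full pipeline
#' (recordings, feature extraction, PCA, subregion averaging, exam
#' z-scores, stepwise exam prediction), and checks whether (a) the
#' stepwise model retains a term of the component dominated by the
#' scaling-exponent features with a negative coefficient and (b) the
#' stepwise model's AIC beats the background-type model's.
#'
#' The cohort conditions are fixed study choices: 16 participants, 8
#' lecture topics (2 per background), 45 s fragments at 256 Hz, 6
#' channels (one per subregion), and a feature registry without the
#' alpha-peak estimators (those are validated separately).
#'
#' @param n_seeds Number of simulated cohorts.
#' @param seed Master seed.
#' @param n_participants,duration_s,fs,n_channels Cohort scale.
#' @return Data frame per seed: `lrtc_dominance` (% contribution of the
#'   SEV features to the most LRTC-driven PC), `retained`, `negative`,
#'   `aic_beats_background`, `aic_stepwise`, `aic_background`.
#' @export
recover_exam_prediction <- function(n_seeds = 20, seed = 1,
                                    n_participants = 16, duration_s = 45,
                                    fs = 256, n_channels = 6) {
  set.seed(seed)
  cohort_seeds <- sample.int(2^30, n_seeds)
  reg <- feature_registry()
  reg <- reg[!reg$name %in% c("MF2713", "MF2813", "MP2713", "MP2813", "IAF",
                              paste0("SEF95_", c("delta", "theta", "alpha",
                                                 "beta", "gamma"))), ]
  rows <- lapply(seq_len(n_seeds), function(i) {
    spec <- cohort_spec(n_participants, tasks = "LA", fs = fs,
                        n_channels = n_channels,
                        fragment_duration_s = c(LA = duration_s),
                        topics_per_background = 2, seed = cohort_seeds[i])
    osc <- oscillator_spec(10, peak_power = 4, bandwidth_hz = 2,
                           envelope_hurst = 0.72, envelope_depth = 0.4)
    plan <- effect_plan(
      fixed_shifts = rbind(
        data.frame(task = "LA", background = c("MT", "HW", "FT"),
                   parameter = "envelope_hurst",
                   shift = c(-0.15, -0.08, -0.04)),
        data.frame(task = "LA", background = c("MT", "HW", "FT"),
                   parameter = "alpha_log_power",
                   shift = c(0.4, 0.25, 0.1))
      ),
      participant_sd = c(alpha_log_power = 0.2, envelope_hurst = 0.05,
                         alpha_center_hz = 0.3),
      fragment_sd = c(alpha_log_power = 0.05, envelope_hurst = 0.05,
                      alpha_center_hz = 0.05),
      exam_weights = c(envelope_hurst = -3),
      exam_noise_sd = 1, exam_participant_sd = 1
    )
    cohort <- simulate_cohort(spec, osc, plan)
    ft <- cohort_features(cohort, reg, nfft = 1024)
    fm <- build_matrix(ft, reg)
    pca <- fit_pca(fm)
    ss <- subregion_scores(pca, subregion_map(scalp_labels(n_channels)), k = 9)
    examz <- exam_zscores(generate_exam_table(cohort))
    pe <- predict_exam(examz, ss[ss$task == "LA", ], mode = "fixed", k = 9)
    lc <- lrtc_contribution(pca)[paste0("PC", 1:9)]
    top <- names(which.max(lc))
    ret <- grep(paste0("^", top, "_"), pe$stepwise$retained, value = TRUE)
    cf <- pe$fits$eeg_stepwise$coefficients
    est <- cf$estimate[match(ret, cf$term)]
    data.frame(
      lrtc_dominance = unname(max(lc)),
      retained = length(ret) > 0,
      negative = length(est) > 0 && est[which.max(abs(est))] < 0,
      aic_beats_background =
        unname(pe$aic["eeg_stepwise"] < pe$aic["background"]),
      aic_stepwise = unname(pe$aic["eeg_stepwise"]),
      aic_background = unname(pe$aic["background"])
    )
  })
  do.call(rbind, rows)
}

#' Audio-EEG delay recovery study
#'
#' Plants known delays on the simulated sound channel and measures exact
#' recovery for a clean copy and recovery under 0 dB SNR noise.
#'
#' @param delay Planted delay (samples) for the noisy condition.
#' @param n_seeds Noisy replicates.
#' @param duration_s,fs Audio size.
#' @param seed Master seed.
#' @return List: `clean_exact` (delays 0 and 100 recovered exactly),
#'   `noisy_correct` (count of exact recoveries at 0 dB), `n_seeds`.
#' @export
recover_delay <- function(delay = 137, n_seeds = 10, duration_s = 20,
                          fs = 256, seed = 1) {
  set.seed(seed)
  n <- round(duration_s * fs)
  make_audio <- function() {
    bf <- signal::butter(4, 0.4)
    signal::filtfilt(bf, rnorm(n))
  }
  base <- generate_recording(duration_s, fs, n_channels = 1,
                             keep_envelopes = FALSE)
  audio <- make_audio()
  clean <- vapply(c(0, 100), function(d) {
    rec <- generate_sync_channel(base$recording, audio, d)
    estimate_delay(rec$data["Sound", ], audio)
  }, numeric(1))
  noisy <- replicate(n_seeds, {
    audio_i <- make_audio()
    rec <- generate_sync_channel(base$recording, audio_i, delay,
                                 noise_sd = sd(audio_i)) # 0 dB SNR
    estimate_delay(rec$data["Sound", ], audio_i)
  })
  list(clean_exact = identical(unname(clean), c(0, 100)),
       noisy_correct = sum(noisy == delay), n_seeds = n_seeds)
}
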