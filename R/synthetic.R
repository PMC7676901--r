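#' Oscillator specification for synthetic EEG
#'
#' Describes one narrowband oscillatory component planted into a
#' synthetic recording: a spectral bump of known center frequency, total
#' power, and bandwidth, whose amplitude envelope is offset fractional
#' Gaussian noise with a chosen Hurst exponent. The carrier is the
#' phase-normalized analytic signal of narrowband-filtered white noise
#' (unit modulus), so the planted envelope is exactly the Hilbert
#' amplitude envelope of the component while the spectrum keeps a
#' bump of the requested width.
#'
#' @param center_hz Center frequency of the spectral bump (Hz).
#' @param peak_power Total power (variance, uV^2) of the oscillation.
#' @param bandwidth_hz Width of the band-pass used to shape the carrier
#'   (Hz); approximately the -3 dB width of the resulting bump.
#' @param envelope_hurst Hurst exponent of the amplitude envelope,
#'   strictly inside (0, 1).
#' @param envelope_depth Modulation depth: the envelope is
#'   `1 + depth * fGn`, floored at 0.05 to stay strictly positive.
#' @param region_weights Optional named numeric vector of per-subregion
#'   gains (names among the six subregions); unnamed regions get gain 1.
#' @return Object of class `oscillator_spec`.
#' @export
oscillator_spec <- function(center_hz, peak_power = 4, bandwidth_hz = 2,
                            envelope_hurst = 0.7, envelope_depth = 0.4,
                            region_weights = NULL) {
  if (envelope_hurst <= 0 || envelope_hurst >= 1) {
    stop("envelope_hurst must lie strictly inside (0, 1)")
  }
  if (bandwidth_hz <= 0) stop("bandwidth_hz must be positive")
  if (center_hz <= bandwidth_hz / 2) stop("center_hz too low for its bandwidth")
  structure(
    list(center_hz = center_hz, peak_power = peak_power,
         bandwidth_hz = bandwidth_hz, envelope_hurst = envelope_hurst,
         envelope_depth = envelope_depth, region_weights = region_weights),
    class = "oscillator_spec"
  )
}

#' Cohort specification for synthetic listening experiments
#'
#' Encodes the design of the listening study the simulator emulates:
#' participants hear lectures in noise (task LA) in every background,
#' and attend (BA) or ignore (BUA) the backgrounds themselves in the
#' noise-only backgrounds, giving the usual ten listening conditions
#' with the defaults.
#'
#' @param n_participants Number of participants (>= 1).
#' @param tasks Listening tasks, subset of `c("LA", "BA", "BUA")`.
#' @param backgrounds Background sounds, subset of
#'   `c("PK", "MT", "HW", "FT")` (pink noise = lecture in silence,
#'   multi-talker, highway, fluctuating traffic).
#' @param fragment_duration_s Named numeric with per-task fragment
#'   durations in seconds (defaults: LA 300 s, BA/BUA 180 s).
#' @param fs Sampling rate (Hz).
#' @param n_channels Number of scalp channels.
#' @param topics_per_background Lecture topics per background in the LA
#'   task; topics rotate over backgrounds across participants so every
#'   topic is heard in silence by a share of the cohort.
#' @param seed Master seed; all randomness in the cohort flows from it.
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_participants, tasks = c("LA", "BA", "BUA"),
                        backgrounds = c("PK", "MT", "HW", "FT"),
                        fragment_duration_s = c(LA = 300, BA = 180, BUA = 180),
                        fs = 512, n_channels = 64,
                        topics_per_background = 1, seed = 1L) {
  stopifnot(n_participants >= 1, fs > 0, n_channels >= 6)
  tasks <- match.arg(tasks, c("LA", "BA", "BUA"), several.ok = TRUE)
  backgrounds <- match.arg(backgrounds, c("PK", "MT", "HW", "FT"), several.ok = TRUE)
  if (!all(tasks %in% names(fragment_duration_s))) {
    stop("fragment_duration_s must name every task")
  }
  structure(
    list(n_participants = n_participants, tasks = tasks,
         backgrounds = backgrounds, fragment_duration_s = fragment_duration_s,
         fs = fs, n_channels = n_channels,
         topics_per_background = topics_per_background, seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

#' Effect plan: planted condition, participant, and exam structure
#'
#' Describes how the planted generator parameters vary across conditions
#' and participants, and how exam scores are produced from the planted
#' latent features. Parameters that can be shifted are
#' `"alpha_log_power"` (log of the alpha oscillator power),
#' `"alpha_center_hz"`, `"envelope_hurst"`, and `"onef_exponent"`.
#'
#' @param fixed_shifts Data frame with columns `task`, `background`,
#'   `parameter`, `shift`: additive shifts applied to the named planted
#'   parameter in that condition cell (use `"*"` to match any level).
#' @param participant_sd Named numeric: SD of Gaussian per-participant
#'   intercepts on each parameter.
#' @param fragment_sd Named numeric: SD of per-fragment jitter.
#' @param exam_weights Named numeric: linear weights of the z-scored
#'   planted latent parameters in the exam-score model.
#' @param exam_noise_sd SD of the exam residual noise (keywords).
#' @param exam_participant_sd SD of the per-participant exam intercept.
#' @param exam_base Mean keywords correct in the reference condition.
#' @param exam_max Maximum keywords per topic (scores are clipped to
#'   `[0, exam_max]` and rounded).
#' @return Object of class `effect_plan`.
#' @export
effect_plan <- function(fixed_shifts = NULL,
                        participant_sd = c(alpha_log_power = 0.2,
                                           envelope_hurst = 0.04,
                                           alpha_center_hz = 0.3),
                        fragment_sd = c(alpha_log_power = 0.05,
                                        envelope_hurst = 0.02,
                                        alpha_center_hz = 0.05),
                        exam_weights = numeric(),
                        exam_noise_sd = 1,
                        exam_participant_sd = 1,
                        exam_base = 10, exam_max = 20) {
  pars <- c("alpha_log_power", "alpha_center_hz", "envelope_hurst", "onef_exponent")
  if (!is.null(fixed_shifts)) {
    stopifnot(all(c("task", "background", "parameter", "shift") %in% names(fixed_shifts)))
    if (!all(fixed_shifts$parameter %in% pars)) {
      stop("unknown parameter in fixed_shifts")
    }
  }
  if (any(participant_sd < 0) || any(fragment_sd < 0) ||
      exam_noise_sd < 0 || exam_participant_sd < 0) {
    stop("scales must be nonnegative")
  }
  structure(
    list(fixed_shifts = fixed_shifts, participant_sd = participant_sd,
         fragment_sd = fragment_sd, exam_weights = exam_weights,
         exam_noise_sd = exam_noise_sd,
         exam_participant_sd = exam_participant_sd,
         exam_base = exam_base, exam_max = exam_max),
    class = "effect_plan"
  )
}

osc_component <- function(n, fs, osc) {
  lo <- osc$center_hz - osc$bandwidth_hz / 2
  hi <- osc$center_hz + osc$bandwidth_hz / 2
  if (hi >= fs / 2) stop("oscillator center_hz/bandwidth at or above Nyquist")
  pad <- min(2 * fs, n)
  wn <- rnorm(n + 2 * pad)
  bf <- signal::butter(2, c(lo, hi) / (fs / 2), type = "pass")
  carrier <- signal::filtfilt(bf, wn)[(pad + 1):(pad + n)]
  a <- analytic_signal(carrier)
  phase <- Re(a / pmax(Mod(a), 1e-12))
  env_fgn <- fgn_sim(n, osc$envelope_hurst)
  env <- pmax(1 + osc$envelope_depth * env_fgn, 0.05)
  x <- phase * env
  list(signal = x * sqrt(osc$peak_power) / sd(x), envelope_fgn = env_fgn)
}

#' Generate a synthetic multichannel EEG recording with known ground truth
#'
#' Each channel is the sum of a scale-free `1/f^beta` background (drawn
#' independently per channel) and the planted oscillators, which are
#' shared sources projected to channels through per-subregion gains.
#'
#' @param duration_s Duration in seconds.
#' @param fs Sampling rate (Hz).
#' @param n_channels Number of scalp channels (labels from
#'   [scalp_labels()]).
#' @param oscillators List of [oscillator_spec()] objects.
#' @param onef_exponent Spectral exponent `beta` of the background
#'   (`P(f) ~ f^-beta`), in `[0, 3]`.
#' @param background_sd Per-channel SD of the background (uV).
#' @param labels Channel labels.
#' @param seed Optional seed (uses the current RNG state if `NULL`).
#' @param keep_envelopes Store the raw envelope fGn of each oscillator in
#'   the ground-truth record (needed by envelope-recovery oracles).
#' @return List with elements `recording` (an [eeg_recording()]) and
#'   `truth` (planted parameter record, including each oscillator's raw
#'   envelope fGn when `keep_envelopes = TRUE`).
#' @export
generate_recording <- function(duration_s, fs = 512, n_channels = 64,
                               oscillators = list(), onef_exponent = 1,
                               background_sd = 1,
                               labels = scalp_labels(n_channels),
                               seed = NULL, keep_envelopes = TRUE) {
  if (onef_exponent < 0 || onef_exponent > 3) {
    stop("onef_exponent must lie in [0, 3]")
  }
  if (inherits(oscillators, "oscillator_spec")) oscillators <- list(oscillators)
  for (o in oscillators) {
    if (o$center_hz >= fs / 2) stop("oscillator center_hz at or above Nyquist")
  }
  if (!is.null(seed)) set.seed(seed)
  n <- round(duration_s * fs)
  regions <- subregion_map(labels)
  data <- matrix(0, nrow = length(labels), ncol = n, dimnames = list(labels, NULL))
  for (ch in seq_along(labels)) {
    data[ch, ] <- onef_noise(n, onef_exponent, fs, sd = background_sd)
  }
  osc_truth <- list()
  for (i in seq_along(oscillators)) {
    o <- oscillators[[i]]
    comp <- osc_component(n, fs, o)
    gains <- rep(1, length(labels))
    if (!is.null(o$region_weights)) {
      gains <- ifelse(regions %in% names(o$region_weights),
                      unname(o$region_weights[regions]), 1)
      gains[is.na(gains)] <- 1
    }
    data <- data + outer(gains, comp$signal)
    osc_truth[[i]] <- list(
      center_hz = o$center_hz, peak_power = o$peak_power,
      bandwidth_hz = o$bandwidth_hz, envelope_hurst = o$envelope_hurst,
      envelope_depth = o$envelope_depth,
      envelope_fgn = if (keep_envelopes) comp$envelope_fgn else NULL
    )
  }
  list(
    recording = eeg_recording(data, fs, labels),
    truth = list(oscillators = osc_truth, onef_exponent = onef_exponent,
                 background_sd = background_sd, fs = fs,
                 duration_s = duration_s)
  )
}

#' Append a delayed copy of the presented audio as a sync channel
#'
#' Emulates the free EEG channel on which the presented sound is
#' recorded: the audio appears `delay_samples` later than in the
#' presentation, optionally with additive Gaussian noise.
#'
#' @param rec An [eeg_recording()].
#' @param audio Numeric vector of presented audio samples (at `rec$fs`).
#' @param delay_samples Integer delay in samples, `0 <= delay < n`.
#' @param noise_sd SD of additive noise on the sound channel.
#' @param label Name of the appended channel.
#' @return A new `eeg_recording` with the sound channel appended and the
#'   true delay stored in attribute `"sync_delay"`.
#' @export
generate_sync_channel <- function(rec, audio, delay_samples, noise_sd = 0,
                                  label = "Sound") {
  n <- n_samples(rec)
  if (delay_samples < 0 || delay_samples >= n) {
    stop("delay_samples must lie in [0, n_samples)")
  }
  chan <- c(rep(0, delay_samples), audio)[seq_len(n)]
  chan[is.na(chan)] <- 0
  if (noise_sd > 0) chan <- chan + rnorm(n, sd = noise_sd)
  out <- eeg_recording(rbind(rec$data, chan), rec$fs,
                       c(rec$labels, label), rec$reference, rec$exclusions)
  attr(out, "sync_delay") <- delay_samples
  out
}

match_shift <- function(plan, task, background, parameter) {
  fs <- plan$fixed_shifts
  if (is.null(fs)) return(0)
  hit <- (fs$task == task | fs$task == "*") &
    (fs$background == background | fs$background == "*") &
    fs$parameter == parameter
  sum(fs$shift[hit])
}

#' Simulate a synthetic listening cohort
#'
#' Lays out the condition manifest (fragments per participant, task,
#' background, lecture topic), draws the planted per-fragment generator
#' parameters (condition shifts + participant intercepts + fragment
#' jitter per the [effect_plan()]), and assigns each fragment a derived
#' RNG substream so any fragment can be realized independently and
#' reproducibly with [realize_fragment()].
#'
#' @param spec A [cohort_spec()].
#' @param oscillators List of base [oscillator_spec()]s; the first is the
#'   alpha oscillator whose parameters the effect plan perturbs.
#' @param plan An [effect_plan()].
#' @param onef_exponent Base background spectral exponent.
#' @param background_sd Background SD (uV).
#' @return Object of class `eeg_cohort` with elements `spec`, `plan`,
#'   `oscillators`, `manifest` (condition manifest data frame), and
#'   `truth` (per-fragment planted parameters).
#' @export
simulate_cohort <- function(spec, oscillators, plan = effect_plan(),
                            onef_exponent = 1, background_sd = 1) {
  if (inherits(oscillators, "oscillator_spec")) oscillators <- list(oscillators)
  set.seed(spec$seed)
  bg <- spec$backgrounds
  nt <- length(bg) * spec$topics_per_background
  topics <- sprintf("T%02d", seq_len(nt))
  participants <- sprintf("P%02d", seq_len(spec$n_participants))

  rows <- list()
  for (p in seq_along(participants)) {
    t0 <- 0
    # LA: lectures in every background; topics rotate across participants
    if ("LA" %in% spec$tasks) {
      perm <- ((seq_len(nt) + p - 2) %% nt) + 1
      tps <- topics[perm]
      for (b in seq_along(bg)) {
        for (k in seq_len(spec$topics_per_background)) {
          dur <- unname(spec$fragment_duration_s["LA"])
          rows[[length(rows) + 1]] <- data.frame(
            participant = participants[p], task = "LA", background = bg[b],
            topic = tps[(b - 1) * spec$topics_per_background + k],
            start_s = t0, stop_s = t0 + dur, stringsAsFactors = FALSE
          )
          t0 <- t0 + dur
        }
      }
    }
    for (task in setdiff(spec$tasks, "LA")) {
      for (b in setdiff(bg, "PK")) { # background tasks only in real noise
        dur <- unname(spec$fragment_duration_s[task])
        rows[[length(rows) + 1]] <- data.frame(
          participant = participants[p], task = task, background = b,
          topic = NA_character_, start_s = t0, stop_s = t0 + dur,
          stringsAsFactors = FALSE
        )
        t0 <- t0 + dur
      }
    }
  }
  manifest <- do.call(rbind, rows)
  manifest$fragment_id <- sprintf("F%04d", seq_len(nrow(manifest)))
  manifest <- manifest[, c("fragment_id", "participant", "task", "background",
                           "topic", "start_s", "stop_s")]

  pars <- c("alpha_log_power", "alpha_center_hz", "envelope_hurst", "onef_exponent")
  psd <- function(nm) if (nm %in% names(plan$participant_sd)) plan$participant_sd[[nm]] else 0
  fsd <- function(nm) if (nm %in% names(plan$fragment_sd)) plan$fragment_sd[[nm]] else 0
  pint <- sapply(pars, function(nm) rnorm(spec$n_participants, sd = psd(nm)))
  rownames(pint) <- participants

  base <- oscillators[[1]]
  truth <- manifest
  for (nm in pars) {
    base_val <- switch(nm,
      alpha_log_power = log(base$peak_power),
      alpha_center_hz = base$center_hz,
      envelope_hurst = base$envelope_hurst,
      onef_exponent = onef_exponent
    )
    shifts <- mapply(function(tk, b) match_shift(plan, tk, b, nm),
                     manifest$task, manifest$background)
    frag_jit <- rnorm(nrow(manifest), sd = fsd(nm))
    truth[[nm]] <- base_val + shifts + pint[manifest$participant, nm] + frag_jit
  }
  truth$envelope_hurst <- pmin(pmax(truth$envelope_hurst, 0.05), 0.95)
  truth$onef_exponent <- pmin(pmax(truth$onef_exponent, 0), 3)
  truth$fragment_seed <- sample.int(.Machine$integer.max - 1, nrow(manifest))
  exam_seed <- sample.int(.Machine$integer.max - 1, 1)

  structure(
    list(spec = spec, plan = plan, oscillators = oscillators,
         onef_exponent = onef_exponent, background_sd = background_sd,
         manifest = manifest, truth = truth, exam_seed = exam_seed),
    class = "eeg_cohort"
  )
}

#' @export
print.eeg_cohort <- function(x, ...) {
  cat(sprintf("<eeg_cohort> %d participants, %d fragments, %d channels @ %g Hz\n",
              x$spec$n_participants, nrow(x$manifest), x$spec$n_channels, x$spec$fs))
  invisible(x)
}

#' Realize one fragment of a simulated cohort as an EEG recording
#'
#' Regenerates the fragment deterministically from its derived RNG
#' substream and the planted per-fragment parameters.
#'
#' @param cohort An `eeg_cohort` from [simulate_cohort()].
#' @param fragment_id Fragment identifier from the manifest.
#' @param keep_envelopes Keep the raw envelope fGn in the ground truth.
#' @return As [generate_recording()]: list of `recording` and `truth`.
#' @export
realize_fragment <- function(cohort, fragment_id, keep_envelopes = FALSE) {
  row <- cohort$truth[cohort$truth$fragment_id == fragment_id, ]
  if (nrow(row) != 1) stop("unknown fragment_id: ", fragment_id)
  osc <- cohort$oscillators
  o1 <- osc[[1]]
  o1$peak_power <- exp(row$alpha_log_power)
  o1$center_hz <- row$alpha_center_hz
  o1$envelope_hurst <- row$envelope_hurst
  osc[[1]] <- o1
  dur <- row$stop_s - row$start_s
  set.seed(row$fragment_seed)
  out <- generate_recording(
    duration_s = dur, fs = cohort$spec$fs,
    n_channels = cohort$spec$n_channels, oscillators = osc,
    onef_exponent = row$onef_exponent, background_sd = cohort$background_sd,
    labels = scalp_labels(cohort$spec$n_channels),
    seed = NULL, keep_envelopes = keep_envelopes
  )
  out$truth$fragment_id <- fragment_id
  out
}

#' Generate an exam table from a cohort's planted latent features
#'
#' Exam scores (keywords correctly retained per participant x topic) are
#' a rounded, clipped linear function of the z-scored planted latent
#' parameters of the corresponding lecture fragment, plus a Gaussian
#' per-participant intercept and residual noise. Topic difficulty is
#' referenced to the silence (pink-noise) condition, so the table always
#' contains pink-noise rows for every topic (guaranteed by the topic
#' rotation in [simulate_cohort()]).
#'
#' @param cohort An `eeg_cohort`.
#' @param seed Seed for the exam noise (defaults to the cohort's derived
#'   exam substream).
#' @return Data frame with columns `participant`, `topic`, `background`,
#'   `keywords_correct`, plus the latent z-scores used (columns prefixed
#'   `latent_`).
#' @export
generate_exam_table <- function(cohort, seed = cohort$exam_seed) {
  la <- cohort$truth[cohort$truth$task == "LA", ]
  if (nrow(la) == 0) stop("cohort has no lecture (LA) fragments")
  if (any(is.na(la$topic))) stop("every LA fragment must carry a topic")
  pk_counts <- table(la$topic[la$background == "PK"])
  missing <- setdiff(unique(la$topic), names(pk_counts))
  if (length(missing) > 0) {
    stop("topics never presented in pink noise: ", paste(missing, collapse = ", "))
  }
  plan <- cohort$plan
  set.seed(seed)
  zs <- function(x) if (sd(x) == 0) rep(0, length(x)) else (x - mean(x)) / sd(x)
  lin <- rep(plan$exam_base, nrow(la))
  lat <- list()
  for (nm in names(plan$exam_weights)) {
    if (!nm %in% names(la)) stop("exam weight references unknown latent: ", nm)
    z <- zs(la[[nm]])
    lat[[paste0("latent_", nm)]] <- z
    lin <- lin + plan$exam_weights[[nm]] * z
  }
  b_p <- rnorm(cohort$spec$n_participants, sd = plan$exam_participant_sd)
  names(b_p) <- sprintf("P%02d", seq_len(cohort$spec$n_participants))
  lin <- lin + b_p[la$participant] + rnorm(nrow(la), sd = plan$exam_noise_sd)
  out <- data.frame(
    participant = la$participant, topic = la$topic,
    background = la$background,
    keywords_correct = pmin(pmax(round(lin), 0), plan$exam_max),
    stringsAsFactors = FALSE
  )
  for (nm in names(lat)) out[[nm]] <- lat[[nm]]
  out
}
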