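#' Re-reference a recording to a named channel
#'
#' Subtracts the reference channel's signal from every channel. The
#' operation is idempotent (re-referencing twice to the same channel
#' changes nothing after the first pass) and leaves channel differences
#' invariant.
#'
#' @param rec An [eeg_recording()].
#' @param ref_label Label of the reference channel; must be present.
#' @return Re-referenced `eeg_recording` with updated reference metadata.
#' @export
rereference <- function(rec, ref_label) {
  if (!ref_label %in% rec$labels) {
    stop("reference channel not found: ", ref_label)
  }
  ref <- rec$data[ref_label, ]
  data <- sweep(rec$data, 2, ref, "-")
  eeg_recording(data, rec$fs, rec$labels, reference = ref_label,
                exclusions = rec$exclusions)
}

# zero-phase application of a linear-phase (symmetric) FIR filter:
# single FFT convolution, group delay (order/2) removed.
fir_zerophase <- function(x, b) {
  n <- length(x)
  ord <- length(b) - 1
  nf <- nextn(n + length(b), 2)
  y <- Re(fft(fft(c(x, numeric(nf - n))) * fft(c(b, numeric(nf - length(b)))),
              inverse = TRUE)) / nf
  y[(ord %/% 2 + 1):(ord %/% 2 + n)]
}

#' Resample and band-pass filter a recording
#'
#' Anti-aliased polyphase resampling to `target_fs`, followed by a
#' zero-phase Hamming-windowed-sinc FIR band-pass. The filter is applied
#' in a single pass (linear phase) with the group delay compensated, so
#' envelope timing is preserved for downstream fluctuation analysis.
#'
#' @param rec An [eeg_recording()].
#' @param target_fs Target sampling rate (Hz), at most the original.
#' @param band Pass band `c(f_lo, f_hi)` in Hz, inside `(0, target_fs/2)`.
#' @param order FIR order (number of taps minus one). The default 3380
#'   corresponds to the sharp transition used for 512 Hz recordings; for
#'   short signals pass a smaller order.
#' @return Filtered `eeg_recording` at `target_fs`.
#' @export
resample_filter <- function(rec, target_fs = 512, band = c(0.5, 134),
                            order = 3380) {
  if (target_fs > rec$fs) stop("target_fs must not exceed the original fs")
  if (band[2] >= target_fs / 2) stop("band edge at or above Nyquist")
  if (band[1] <= 0) stop("lower band edge must be positive")
  data <- rec$data
  if (target_fs < rec$fs) {
    r <- rec$fs / target_fs
    if (abs(r - round(r)) > 1e-9) stop("fs ratio must be an integer")
    data <- t(apply(data, 1, function(x) {
      signal::resample(x, 1, round(r))
    }))
  }
  ntap <- order + 1
  if (ntap >= ncol(data)) stop("filter order too large for signal length")
  b <- signal::fir1(order, band / (target_fs / 2), type = "pass",
                    window = signal::hamming(ntap))
  data <- t(apply(data, 1, fir_zerophase, b = as.numeric(b)))
  out <- eeg_recording(data, target_fs, rec$labels, rec$reference, rec$exclusions)
  attr(out, "filter") <- list(band = band, order = order, window = "hamming")
  out
}

#' Estimate the audio-to-EEG delay by cross-correlation
#'
#' Returns the lag (in samples) at which the cross-correlation between
#' the recorded sound channel and the presented audio is maximal. A
#' positive lag means the audio arrives later in the recording than in
#' the presentation. Ties are broken toward the smallest absolute lag.
#'
#' @param recorded Sound channel recorded together with the EEG.
#' @param presented Presented audio resampled to the same rate.
#' @param max_lag_s Optional maximum |lag| to search, in seconds (needs
#'   `fs`); unrestricted if `NULL`.
#' @param fs Sampling rate (only used with `max_lag_s`).
#' @return Integer lag in samples.
#' @export
estimate_delay <- function(recorded, presented, max_lag_s = NULL, fs = NULL) {
  if (sd(recorded) == 0 || sd(presented) == 0) {
    stop("cross-correlation undefined for constant input")
  }
  n <- max(length(recorded), length(presented))
  if (n < 2) stop("inputs too short")
  a <- c(recorded, numeric(n - length(recorded)))
  b <- c(presented, numeric(n - length(presented)))
  nf <- nextn(2 * n, 2)
  cc <- Re(fft(fft(c(a, numeric(nf - n))) * Conj(fft(c(b, numeric(nf - n)))),
               inverse = TRUE)) / nf
  lags <- c(0:(nf / 2 - 1), -(nf / 2):-1)
  keep <- abs(lags) < n
  if (!is.null(max_lag_s)) {
    if (is.null(fs)) stop("fs required with max_lag_s")
    keep <- keep & abs(lags) <= max_lag_s * fs
  }
  cc <- cc[keep]
  lags <- lags[keep]
  best <- cc >= max(cc) - 1e-12 * max(abs(cc))
  cand <- lags[best]
  cand[which.min(abs(cand))]
}

#' Split a recording into condition fragments
#'
#' Cuts the recording at the manifest's start/stop times (seconds) and
#' returns one sub-recording per manifest row together with its
#' condition tags.
#'
#' @param rec An [eeg_recording()].
#' @param manifest Data frame with at least `start_s` and `stop_s`
#'   columns; any other columns are carried along as tags.
#' @return List of lists, each with elements `recording` and `tags`.
#' @export
split_fragments <- function(rec, manifest) {
  if (nrow(manifest) == 0) return(list())
  n <- n_samples(rec)
  starts <- round(manifest$start_s * rec$fs) + 1
  stops <- round(manifest$stop_s * rec$fs)
  if (any(starts < 1) || any(stops > n)) stop("fragment interval out of range")
  ord <- order(starts)
  if (any(starts[ord][-1] < stops[ord][-length(ord)] + 1 - 1e-9)) {
    stop("fragments overlap")
  }
  lapply(seq_len(nrow(manifest)), function(i) {
    sub <- rec$data[, starts[i]:stops[i], drop = FALSE]
    list(
      recording = eeg_recording(sub, rec$fs, rec$labels, rec$reference),
      tags = manifest[i, setdiff(names(manifest), c("start_s", "stop_s")),
                      drop = FALSE]
    )
  })
}

#' Read a condition manifest from CSV
#'
#' @param path CSV with named columns including `participant`, `task`,
#'   `background`, `start_s`, `stop_s` (and optionally `topic`).
#' @return Data frame.
#' @export
read_manifest <- function(path) {
  m <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("participant", "task", "background", "start_s", "stop_s")
  if (!all(need %in% names(m))) {
    stop("manifest must contain columns: ", paste(need, collapse = ", "))
  }
  m
}

#' Read channel/interval exclusion lists from CSV
#'
#' Exclusions replace the manual artifact-rejection steps of a typical
#' EEG workflow: rows name either a channel to drop or a time interval
#' (`start_s`, `stop_s`) to ignore, per participant.
#'
#' @param path CSV with columns `participant`, `channel` (may be empty),
#'   `start_s`, `stop_s` (may be empty).
#' @return Data frame.
#' @export
read_exclusions <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}
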