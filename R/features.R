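#' Default feature registry
#'
#' Names every per-channel feature the extraction stage can compute and
#' whether it is log-transformed before PCA (natural log; applied to
#' absolute and peak powers only). The registry is an ordinary data
#' frame: drop rows to compute a subset (e.g. omitting the root-MUSIC
#' and IAF features for large simulation studies), or reorder freely.
#'
#' @param include Optional character vector of feature names to keep.
#' @return Data frame with columns `name` and `log_transform`.
#' @export
feature_registry <- function(include = NULL) {
  shape_bands <- c("delta", "theta", "alpha", "beta", "gamma")
  reg <- rbind(
    data.frame(name = paste0("AP_", band_definitions()$name), log_transform = TRUE),
    data.frame(name = paste0("RP_", shape_bands), log_transform = FALSE),
    data.frame(name = "RPTA", log_transform = FALSE),
    data.frame(name = paste0("CF_", shape_bands), log_transform = FALSE),
    data.frame(name = paste0("B_", shape_bands), log_transform = FALSE),
    data.frame(name = paste0("SEF95_", shape_bands), log_transform = FALSE),
    data.frame(name = c("MF2713", "MF2813"), log_transform = FALSE),
    data.frame(name = c("MP2713", "MP2813"), log_transform = TRUE),
    data.frame(name = "IAF", log_transform = FALSE),
    data.frame(name = c("SEV1", "SEV2"), log_transform = FALSE)
  )
  if (!is.null(include)) {
    missing <- setdiff(include, reg$name)
    if (length(missing) > 0) stop("unknown features: ", paste(missing, collapse = ", "))
    reg <- reg[reg$name %in% include, ]
  }
  rownames(reg) <- NULL
  reg
}

extract_channel_features <- function(x, fs, wanted, nfft = 2^14) {
  out <- numeric(0)
  shape_bands <- c("delta", "theta", "alpha", "beta", "gamma")
  need_psd <- any(grepl("^(AP|RP|RPTA|CF|B|SEF95)", wanted))
  if (need_psd) {
    psd <- welch_psd(x, fs, nfft = nfft)
    bp <- band_powers(psd)
    out <- c(out,
             setNames(bp$AP, paste0("AP_", names(bp$AP))),
             setNames(bp$RP[shape_bands], paste0("RP_", shape_bands)),
             RPTA = bp$RPTA)
    bd <- band_definitions()
    for (b in shape_bands) {
      row <- bd[bd$name == b, ]
      sh <- spectral_shape(psd, c(row$f_lo, row$f_hi))
      out <- c(out, setNames(sh, paste0(c("CF_", "B_", "SEF95_"), b)))
    }
  }
  if (any(c("MF2713", "MP2713") %in% wanted)) {
    rm1 <- rootmusic_peak(x, fs, band = c(7, 13))
    out <- c(out, MF2713 = rm1$MF, MP2713 = rm1$MP)
  }
  if (any(c("MF2813", "MP2813") %in% wanted)) {
    rm2 <- rootmusic_peak(x, fs, band = c(8, 13))
    out <- c(out, MF2813 = rm2$MF, MP2813 = rm2$MP)
  }
  if ("IAF" %in% wanted) {
    ia <- fit_iaf(psd_fine(x, fs))
    out <- c(out, IAF = if (isTRUE(ia$accepted)) ia$IAF else NA_real_)
  }
  if (any(c("SEV1", "SEV2") %in% wanted)) {
    out <- c(out, sev_features(x, fs))
  }
  out[wanted]
}

#' Extract the per-channel feature set of one recording fragment
#'
#' @param rec An [eeg_recording()] (one fragment).
#' @param registry Feature registry (see [feature_registry()]).
#' @param channels Channels to process (default: all).
#' @param nfft Welch FFT length for the band-power spectra; `2^14` for
#'   full-resolution runs, smaller powers of two for large simulation
#'   studies (band powers are insensitive to the grid well below this).
#' @return Data frame, one row per channel, columns `channel` plus the
#'   registry features.
#' @export
extract_features <- function(rec, registry = feature_registry(),
                             channels = rec$labels, nfft = 2^14) {
  wanted <- registry$name
  rows <- lapply(channels, function(ch) {
    v <- extract_channel_features(rec$data[ch, ], rec$fs, wanted, nfft = nfft)
    cbind(data.frame(channel = ch, stringsAsFactors = FALSE),
          as.data.frame(as.list(v)))
  })
  do.call(rbind, rows)
}

#' Extract features for every fragment of a simulated cohort
#'
#' Fragments are realized one at a time from their RNG substreams and
#' discarded after extraction, so memory stays flat regardless of cohort
#' size.
#'
#' @param cohort An `eeg_cohort` from [simulate_cohort()].
#' @param registry Feature registry.
#' @param channels Channels to process (default: all in the montage).
#' @param tasks Optional subset of tasks to extract.
#' @param nfft Welch FFT length (see [extract_features()]).
#' @param verbose Print progress per fragment.
#' @return Long-format feature table: one row per (fragment, channel),
#'   keyed by `participant`, `fragment_id`, `task`, `background`,
#'   `topic`, `channel`.
#' @export
cohort_features <- function(cohort, registry = feature_registry(),
                            channels = NULL, tasks = NULL, nfft = 2^14,
                            verbose = FALSE) {
  man <- cohort$manifest
  if (!is.null(tasks)) man <- man[man$task %in% tasks, ]
  rows <- vector("list", nrow(man))
  for (i in seq_len(nrow(man))) {
    fr <- realize_fragment(cohort, man$fragment_id[i])
    ch <- if (is.null(channels)) fr$recording$labels else channels
    feats <- extract_features(fr$recording, registry, ch, nfft = nfft)
    key <- man[i, c("participant", "fragment_id", "task", "background", "topic")]
    rows[[i]] <- cbind(key[rep(1, nrow(feats)), ], feats, row.names = NULL)
    if (verbose) message(sprintf("extracted %s (%d/%d)", man$fragment_id[i], i, nrow(man)))
  }
  do.call(rbind, rows)
}
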