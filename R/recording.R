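#' EEG recording container
#'
#' Lightweight container for a multichannel recording: a channels x
#' samples matrix in microvolts plus sampling rate, channel labels,
#' reference metadata and optional exclusion lists.
#'
#' @param data Numeric matrix, channels x samples. Row names, if absent,
#'   are taken from `labels`.
#' @param fs Sampling rate in Hz.
#' @param labels Channel labels (unique).
#' @param reference Label of the reference channel, or `NA` if unknown.
#' @param exclusions Optional list with elements `channels` (character)
#'   and `intervals` (two-column matrix of start/stop seconds).
#' @return Object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, fs, labels = rownames(data),
                          reference = NA_character_, exclusions = NULL) {
  data <- as.matrix(data)
  if (is.null(labels)) labels <- paste0("CH", seq_len(nrow(data)))
  if (anyDuplicated(labels)) stop("channel labels must be unique")
  if (length(labels) != nrow(data)) stop("labels must match rows of data")
  if (!is.numeric(fs) || fs <= 0) stop("fs must be positive")
  rownames(data) <- labels
  structure(
    list(data = data, fs = fs, labels = labels,
         reference = reference, exclusions = exclusions),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf(
    "<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s), reference: %s\n",
    nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs,
    ifelse(is.na(x$reference), "<none>", x$reference)
  ))
  invisible(x)
}

#' Number of samples in a recording
#' @param rec An `eeg_recording`.
#' @return Integer sample count.
#' @export
n_samples <- function(rec) ncol(rec$data)
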