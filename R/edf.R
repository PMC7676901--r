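#' Write a recording to an EDF file
#'
#' Minimal European Data Format writer (16-bit integer samples, one
#' continuous data record per second). Each channel is scaled to its own
#' physical min/max, so the quantization step is (max-min)/65535 per
#' channel. Intended for interchange of synthetic and preprocessed
#' recordings; not a full EDF+ implementation (no annotations).
#'
#' @param rec An [eeg_recording()].
#' @param path Output file path.
#' @param patient,recording_id Free-text header fields.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path, patient = "X", recording_id = "synthetic") {
  ns <- length(rec$labels)
  fs <- rec$fs
  if (abs(fs - round(fs)) > 1e-9) stop("EDF writer requires integer fs")
  fs <- round(fs)
  n <- n_samples(rec)
  n_rec <- n %/% fs
  if (n_rec < 1) stop("recording shorter than one EDF record (1 s)")
  data <- rec$data[, seq_len(n_rec * fs), drop = FALSE]

  pmin_ <- apply(data, 1, min)
  pmax_ <- apply(data, 1, max)
  flat <- pmax_ - pmin_ < 1e-12
  pmin_[flat] <- pmin_[flat] - 1
  pmax_[flat] <- pmax_[flat] + 1

  fmt <- function(x, w) {
    s <- substr(formatC(as.character(x), width = w, flag = "-"), 1, w)
    s
  }
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    fmt("0", 8), fmt(patient, 80), fmt(recording_id, 80),
    fmt(format(Sys.Date(), "%d.%m.%y"), 8), fmt("00.00.00", 8),
    fmt(as.character(256 * (ns + 1)), 8), fmt("", 44),
    fmt(as.character(n_rec), 8), fmt("1", 8), fmt(as.character(ns), 4)
  )
  writeChar(hdr, con, nchars = nchar(hdr), eos = NULL)
  fields <- list(
    c(rec$labels),                         # 16
    rep("", ns),                           # 80 transducer
    rep("uV", ns),                         # 8  dimension
    formatC(pmin_, format = "g", digits = 7),  # 8
    formatC(pmax_, format = "g", digits = 7),  # 8
    rep("-32768", ns),                     # 8
    rep("32767", ns),                      # 8
    rep("", ns),                           # 80 prefilter
    rep(as.character(fs), ns),             # 8
    rep("", ns)                            # 32 reserved
  )
  widths <- c(16, 80, 8, 8, 8, 8, 8, 80, 8, 32)
  for (i in seq_along(fields)) {
    s <- paste0(vapply(fields[[i]], fmt, character(1), w = widths[i]), collapse = "")
    writeChar(s, con, nchars = nchar(s), eos = NULL)
  }
  scale <- (pmax_ - pmin_) / 65535
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * fs + 1):(r * fs)
    for (ch in seq_len(ns)) {
      dig <- round((data[ch, idx] - pmin_[ch]) / scale[ch]) - 32768
      writeBin(as.integer(pmin(pmax(dig, -32768), 32767)), con,
               size = 2, endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF file into a recording
#'
#' Reads continuous 16-bit EDF files as produced by [write_edf()] (and
#' plain EDF exports generally, assuming a uniform sampling rate across
#' channels and no annotation channel).
#'
#' @param path EDF file path.
#' @return An [eeg_recording()].
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) {
    raw <- readBin(con, "raw", w)
    trimws(rawToChar(raw))
  }
  rd(8) # version
  rd(80); rd(80); rd(8); rd(8)
  rd(8) # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- vapply(seq_len(ns), function(i) rd(16), character(1))
  for (i in seq_len(ns)) rd(80)
  for (i in seq_len(ns)) rd(8)
  pmin_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  pmax_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  dmin_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  dmax_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  for (i in seq_len(ns)) rd(80)
  spr <- vapply(seq_len(ns), function(i) as.integer(rd(8)), integer(1))
  for (i in seq_len(ns)) rd(32)
  if (length(unique(spr)) != 1) stop("channels with mixed sampling rates unsupported")
  fs <- spr[1] / dur
  scale <- (pmax_ - pmin_) / (dmax_ - dmin_)
  data <- matrix(0, nrow = ns, ncol = n_rec * spr[1])
  for (r in seq_len(n_rec)) {
    for (ch in seq_len(ns)) {
      dig <- readBin(con, "integer", spr[ch], size = 2, endian = "little")
      data[ch, ((r - 1) * spr[1] + 1):(r * spr[1])] <-
        (dig - dmin_[ch]) * scale[ch] + pmin_[ch]
    }
  }
  eeg_recording(data, fs, labels)
}
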