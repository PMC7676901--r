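#' Welch power spectral density estimate
#'
#' Hamming-tapered, overlap-averaged periodogram, zero-padded to `nfft`
#' points. The one-sided density is scaled so that its rectangle-rule
#' integral over frequency equals the signal variance (Parseval), i.e.
#' units are uV^2/Hz.
#'
#' @param x Single-channel samples.
#' @param fs Sampling rate (Hz).
#' @param window_s Window length in seconds.
#' @param overlap_s Window overlap in seconds.
#' @param nfft FFT length (zero-padded); defaults to `2^14`. Must be at
#'   least the window length in samples.
#' @param demean Subtract each segment's mean before tapering.
#' @return Object of class `psd_estimate`: list with `freq` (Hz grid from
#'   0 to fs/2), `power` (uV^2/Hz), and `params`.
#' @export
welch_psd <- function(x, fs, window_s = 1, overlap_s = 0.5, nfft = 2^14,
                      demean = TRUE) {
  L <- round(window_s * fs)
  if (length(x) < L) stop("signal shorter than one window")
  step <- L - round(overlap_s * fs)
  if (step < 1) stop("overlap must be smaller than the window")
  if (nfft < L) nfft <- 2^ceiling(log2(L))
  w <- 0.54 - 0.46 * cos(2 * pi * (0:(L - 1)) / (L - 1))
  U <- sum(w^2) * fs
  starts <- seq(1, length(x) - L + 1, by = step)
  segs <- vapply(starts, function(s) {
    seg <- x[s:(s + L - 1)]
    if (demean) seg <- seg - mean(seg)
    c(seg * w, numeric(nfft - L))
  }, numeric(nfft))
  P <- rowMeans(Mod(mvfft(segs))^2) / U
  half <- floor(nfft / 2) + 1
  p <- P[seq_len(half)]
  p[2:(half - 1)] <- 2 * p[2:(half - 1)]
  structure(
    list(freq = seq(0, fs / 2, length.out = half), power = p,
         params = list(window_s = window_s, overlap_s = overlap_s,
                       nfft = nfft, fs = fs, n_segments = length(starts))),
    class = "psd_estimate"
  )
}

#' @export
print.psd_estimate <- function(x, ...) {
  cat(sprintf("<psd_estimate> %d bins, 0-%g Hz (df = %g Hz), %d segments\n",
              length(x$freq), max(x$freq), x$freq[2] - x$freq[1],
              x$params$n_segments))
  invisible(x)
}

#' Construct a PSD object from an explicit spectrum
#'
#' Wraps a frequency grid and power values (e.g. an analytically
#' constructed spectrum) in the container used by the feature functions.
#'
#' @param freq Strictly increasing Hz grid.
#' @param power Nonnegative power density values.
#' @return A `psd_estimate`.
#' @export
as_psd <- function(freq, power) {
  stopifnot(length(freq) == length(power), all(diff(freq) > 0),
            all(power >= 0))
  structure(list(freq = freq, power = power, params = list(constructed = TRUE)),
            class = "psd_estimate")
}

#' Canonical frequency band definitions
#'
#' The fixed bands: delta (1-4), theta (4-8), alpha (8-13), alpha7
#' (7-13), lower alpha (8-10), upper alpha (10-13), beta (13-30), gamma
#' (30-45), and the wide band (1-45 Hz).
#'
#' @return Data frame with columns `name`, `f_lo`, `f_hi`.
#' @export
band_definitions <- function() {
  data.frame(
    name = c("delta", "theta", "alpha", "alpha7", "lower_alpha",
             "upper_alpha", "beta", "gamma", "wide"),
    f_lo = c(1, 4, 8, 7, 8, 10, 13, 30, 1),
    f_hi = c(4, 8, 13, 13, 10, 13, 30, 45, 45),
    stringsAsFactors = FALSE
  )
}

# rectangle-rule integral over the half-open band [lo, hi) so adjacent
# bands never double count a shared edge and partitions sum exactly
band_integral <- function(psd, lo, hi) {
  df <- psd$freq[2] - psd$freq[1]
  sel <- psd$freq >= lo & psd$freq < hi
  sum(psd$power[sel]) * df
}

#' Absolute and relative band powers
#'
#' Absolute power (AP) is the integral of the PSD over each band;
#' relative power (RP) divides by the wide-band (1-45 Hz) power; RPTA is
#' the theta/alpha power ratio. Band integrals use half-open bins
#' `[f_lo, f_hi)` so bands that partition 1-45 Hz have RP summing to 1.
#'
#' @param psd A `psd_estimate`.
#' @param bands Data frame as from [band_definitions()].
#' @return List with named numeric vectors `AP`, `RP`, and scalar `RPTA`.
#' @export
band_powers <- function(psd, bands = band_definitions()) {
  if (max(psd$freq) < max(bands$f_hi)) stop("PSD does not cover the bands")
  AP <- setNames(
    mapply(function(lo, hi) band_integral(psd, lo, hi), bands$f_lo, bands$f_hi),
    bands$name
  )
  wide <- band_integral(psd, 1, 45)
  if (wide <= 0) stop("zero wide-band (1-45 Hz) power")
  RP <- AP / wide
  th <- band_integral(psd, 4, 8)
  al <- band_integral(psd, 8, 13)
  if (al <= 0) stop("zero alpha power in theta/alpha ratio")
  list(AP = AP, RP = RP, RPTA = th / al)
}

#' Spectral shape descriptors of one band
#'
#' Central frequency (CF) is the power-weighted center of gravity of the
#' band; bandwidth (B) the root second central spectral moment; SEF95
#' the smallest grid frequency below which 95% of the band power lies.
#'
#' @param psd A `psd_estimate`.
#' @param band Length-2 numeric `c(f_lo, f_hi)`.
#' @return Named numeric vector `c(CF, B, SEF95)`.
#' @export
spectral_shape <- function(psd, band) {
  sel <- psd$freq >= band[1] & psd$freq < band[2]
  f <- psd$freq[sel]
  p <- psd$power[sel]
  tot <- sum(p)
  if (tot <= 0) stop("zero power in band")
  cf <- sum(f * p) / tot
  bw <- sqrt(sum((f - cf)^2 * p) / tot)
  cum <- cumsum(p) / tot
  sef <- f[which(cum >= 0.95)[1]]
  c(CF = cf, B = bw, SEF95 = sef)
}
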