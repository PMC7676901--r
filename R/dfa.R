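#' Alpha-band amplitude envelope
#'
#' Band-passes the signal with a Hamming-windowed FIR filter of order
#' `round(order_s * fs)` taps (0.25 s covers two cycles of the 8 Hz band
#' edge) applied zero-phase, then returns the magnitude of the analytic
#' signal.
#'
#' @param x Single-channel samples.
#' @param fs Sampling rate (Hz).
#' @param band Pass band (Hz), default the 8-13 Hz alpha band.
#' @param order_s FIR filter order expressed in seconds.
#' @return Nonnegative envelope samples, same length as `x`.
#' @export
alpha_envelope <- function(x, fs, band = c(8, 13), order_s = 0.25) {
  ord <- round(order_s * fs)
  if (ord %% 2 == 1) ord <- ord + 1 # even order keeps integer group delay
  if (length(x) < 2 * ord) stop("fragment shorter than twice the filter order")
  b <- signal::fir1(ord, band / (fs / 2), type = "pass",
                    window = signal::hamming(ord + 1))
  xf <- fir_zerophase(x, as.numeric(b))
  Mod(analytic_signal(xf))
}

#' Detrended fluctuation analysis
#'
#' Computes the DFA scaling exponent of a (typically amplitude-envelope)
#' series: the envelope is mean-centered and cumulatively summed into
#' the signal profile; for each of a set of log-spaced window sizes the
#' profile is cut into 50%-overlapping windows (all placements starting
#' at the first sample; a trailing remainder that does not fit is
#' discarded), each window is linearly detrended by least squares, and
#' the fluctuation function is the mean standard deviation over windows.
#' The scaling exponent is the slope of log fluctuation versus log
#' window size by linear regression inside the fit range.
#'
#' @param envelope Envelope samples.
#' @param fs Sampling rate (Hz).
#' @param calc_range_s Calculation range of window sizes, seconds
#'   (classically `c(2.5, 180)` or `c(0.1, 180)`); capped at the signal
#'   length.
#' @param fit_range_s Fit interval for the log-log slope, seconds.
#' @param n_per_decade Number of log-spaced window sizes per decade.
#' @param overlap Window overlap fraction.
#' @return Object of class `dfa_result`: list with `sev` (scaling
#'   exponent), `window_sizes_s`, `fluctuation`, and `fit_r2`.
#' @export
dfa <- function(envelope, fs, calc_range_s = c(2.5, 180),
                fit_range_s = c(5, 18), n_per_decade = 20, overlap = 0.5) {
  if (sd(envelope) == 0) stop("constant envelope: fluctuation undefined")
  if (fit_range_s[1] < calc_range_s[1] || fit_range_s[2] > calc_range_s[2]) {
    stop("fit range must lie inside the calculation range")
  }
  x <- cumsum(envelope - mean(envelope))
  n <- length(x)
  lmax <- min(round(calc_range_s[2] * fs), n)
  lmin <- max(round(calc_range_s[1] * fs), 4)
  if (lmin >= lmax) stop("calculation range too narrow for this signal")
  sizes <- unique(round(exp(seq(log(lmin), log(lmax), by = log(10) / n_per_decade))))
  sizes <- sizes[sizes >= 4 & sizes <= n]
  # prefix sums let each window's linearly detrended variance be written
  # in closed form from the 2x2 normal equations, so the fluctuation at
  # every size costs O(number of windows) vector arithmetic
  cx <- c(0, cumsum(x))
  cxi <- c(0, cumsum(x * seq_len(n)))
  cxx <- c(0, cumsum(x^2))
  fl <- vapply(sizes, function(l) {
    step <- max(1, floor(l * (1 - overlap)))
    starts <- seq(1, n - l + 1, by = step)
    e <- starts + l - 1
    Sx <- cx[e + 1] - cx[starts]
    Sxi <- cxi[e + 1] - cxi[starts]
    Sxx <- cxx[e + 1] - cxx[starts]
    Sxt <- Sxi - (starts - 1) * Sx # local time index t = 1..l
    S1 <- l * (l + 1) / 2
    S2 <- l * (l + 1) * (2 * l + 1) / 6
    det <- l * S2 - S1^2
    b <- (l * Sxt - S1 * Sx) / det
    a <- (Sx - b * S1) / l
    rss <- pmax(Sxx - a * Sx - b * Sxt, 0)
    mean(sqrt(rss / l))
  }, numeric(1))
  infit <- sizes >= fit_range_s[1] * fs & sizes <= fit_range_s[2] * fs
  if (sum(infit) < 2) stop("fewer than 2 window sizes inside the fit range")
  fit <- lm(log(fl[infit]) ~ log(sizes[infit]))
  structure(
    list(sev = unname(coef(fit)[2]),
         window_sizes_s = sizes / fs,
         fluctuation = fl,
         fit_r2 = summary(fit)$r.squared,
         fit_range_s = fit_range_s, calc_range_s = calc_range_s),
    class = "dfa_result"
  )
}

#' @export
print.dfa_result <- function(x, ...) {
  cat(sprintf("<dfa_result> SEV = %.3f (fit %g-%g s, R2 = %.4f)\n",
              x$sev, x$fit_range_s[1], x$fit_range_s[2], x$fit_r2))
  invisible(x)
}

#' Long-range temporal correlation flag
#'
#' A scaling exponent strictly between 0.5 and 1 indicates strong
#' long-range temporal correlations.
#'
#' @param sev Scaling exponent (or a `dfa_result`).
#' @return Logical.
#' @export
has_lrtc <- function(sev) {
  if (inherits(sev, "dfa_result")) sev <- sev$sev
  sev > 0.5 & sev < 1
}

#' Alpha-band scaling exponents SEV1 and SEV2 of a signal
#'
#' Full alpha LRTC pipeline for one channel: band-pass, Hilbert
#' envelope, then DFA with the two standard calculation ranges
#' (2.5-180 s and 0.1-180 s) and the 5-18 s fit interval.
#'
#' @param x Single-channel samples.
#' @param fs Sampling rate (Hz).
#' @param band Alpha band (Hz).
#' @param fit_range_s Fit interval (s).
#' @return Named numeric `c(SEV1, SEV2)`.
#' @export
sev_features <- function(x, fs, band = c(8, 13), fit_range_s = c(5, 18)) {
  env <- alpha_envelope(x, fs, band)
  c(SEV1 = dfa(env, fs, c(2.5, 180), fit_range_s)$sev,
    SEV2 = dfa(env, fs, c(0.1, 180), fit_range_s)$sev)
}
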