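#' Fractional Gaussian noise by circulant embedding
#'
#' Exact synthesis of stationary fractional Gaussian noise (fGn) with
#' Hurst exponent `H` via circulant embedding of the fGn autocovariance
#' (Davies-Harte construction). The embedding is padded to a power-of-two
#' length so the FFTs are fast and the circulant eigenvalues are
#' numerically stable; tiny negative eigenvalues from roundoff are
#' clipped to zero.
#'
#' @param n Number of samples.
#' @param H Hurst exponent, strictly inside (0, 1). `H = 0.5` gives white
#'   noise; `0.5 < H < 1` gives long-range correlated increments.
#' @param sd Marginal standard deviation of the series.
#' @return Numeric vector of length `n`.
#' @export
fgn_sim <- function(n, H, sd = 1) {
  if (!is.numeric(H) || length(H) != 1 || H <= 0 || H >= 1) {
    stop("Hurst exponent must lie strictly inside (0, 1)")
  }
  if (n < 1) stop("n must be positive")
  if (n == 1) return(rnorm(1, sd = sd))
  m <- 2^ceiling(log2(n))
  k <- 0:m
  g <- sd^2 / 2 * (abs(k + 1)^(2 * H) - 2 * abs(k)^(2 * H) + abs(k - 1)^(2 * H))
  row <- c(g, rev(g[2:m])) # circulant first row, length 2m
  ev <- Re(fft(row))
  ev[ev < 0] <- 0 # roundoff guard; exact embedding is nonnegative here
  M <- length(row)
  z <- complex(real = rnorm(M), imaginary = rnorm(M))
  Re(fft(sqrt(ev / (2 * M)) * z))[seq_len(n)]
}

#' Gaussian noise with a 1/f^beta power spectrum
#'
#' Spectral synthesis of scale-free background activity: a white complex
#' spectrum is shaped by `f^(-beta/2)` and inverted. `beta = 0` gives
#' white noise, `beta = 1` pink noise, `beta = 2` Brownian-like noise.
#' The output is standardized to the requested standard deviation.
#'
#' @param n Number of samples.
#' @param beta Spectral exponent of the power spectrum `P(f) ~ f^-beta`.
#' @param fs Sampling rate in Hz (sets the frequency grid).
#' @param sd Standard deviation of the output.
#' @return Numeric vector of length `n`.
#' @export
onef_noise <- function(n, beta, fs, sd = 1) {
  if (n < 2) stop("n must be at least 2")
  nf <- 2^ceiling(log2(n))
  f <- seq(0, fs / 2, length.out = nf / 2 + 1)
  amp <- c(0, f[-1]^(-beta / 2))
  half <- complex(real = rnorm(nf / 2 + 1), imaginary = rnorm(nf / 2 + 1)) * amp
  spec <- c(half, Conj(rev(half[2:(nf / 2)])))
  x <- Re(fft(spec, inverse = TRUE))[seq_len(n)]
  if (stats::sd(x) == 0) return(numeric(n))
  x / stats::sd(x) * sd
}

#' Analytic signal via the frequency-domain Hilbert transform
#'
#' @param x Real-valued signal.
#' @return Complex vector `x + i * H(x)` of the same length.
#' @export
analytic_signal <- function(x) {
  n <- length(x)
  X <- fft(x)
  h <- numeric(n)
  h[1] <- 1
  if (n %% 2 == 0) {
    h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[2:((n + 1) / 2)] <- 2
  }
  fft(X * h, inverse = TRUE) / n
}
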