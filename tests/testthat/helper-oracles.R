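# Independent oracles used across tests. These deliberately avoid the
# package's own code paths: plain loops and closed forms only.

# rectangle-rule band integral with the half-open [lo, hi) convention,
# written as an explicit loop
oracle_band_integral <- function(freq, power, lo, hi) {
  df <- freq[2] - freq[1]
  tot <- 0
  for (i in seq_along(freq)) {
    if (freq[i] >= lo && freq[i] < hi) tot <- tot + power[i] * df
  }
  tot
}

oracle_spectral_shape <- function(freq, power, lo, hi) {
  sel <- freq >= lo & freq < hi
  f <- freq[sel]
  p <- power[sel]
  cf <- sum(f * p) / sum(p)
  b <- sqrt(sum((f - cf)^2 * p) / sum(p))
  cum <- 0
  sef <- NA_real_
  tot <- sum(p)
  for (i in seq_along(f)) {
    cum <- cum + p[i]
    if (cum / tot >= 0.95) {
      sef <- f[i]
      break
    }
  }
  c(CF = cf, B = b, SEF95 = sef)
}

# random synthetic PSD: 1/f background plus a few Gaussian bumps
random_psd <- function(freq) {
  beta <- runif(1, 0, 1.5)
  p <- runif(1, 1, 100) * pmax(freq, 0.5)^(-beta)
  for (k in seq_len(sample(1:3, 1))) {
    ctr <- runif(1, 2, 40)
    wid <- runif(1, 0.3, 3)
    amp <- runif(1, 1, 50)
    p <- p + amp * exp(-((freq - ctr) / wid)^2)
  }
  p
}

# periodogram argmax frequency (FFT of the full signal, no taper)
oracle_peak_freq <- function(x, fs, band) {
  n <- length(x)
  pw <- Mod(fft(x - mean(x)))^2
  f <- (0:(n - 1)) * fs / n
  sel <- f >= band[1] & f <= band[2]
  f[sel][which.max(pw[sel])]
}

# direct matrix-based DFA (windowed regression), the slow reference for
# the closed-form prefix-sum implementation
oracle_dfa_sev <- function(envelope, fs, calc_range_s = c(2.5, 180),
                           fit_range_s = c(5, 18), n_per_decade = 20) {
  x <- cumsum(envelope - mean(envelope))
  n <- length(x)
  lmax <- min(round(calc_range_s[2] * fs), n)
  lmin <- max(round(calc_range_s[1] * fs), 4)
  sizes <- unique(round(exp(seq(log(lmin), log(lmax), by = log(10) / n_per_decade))))
  sizes <- sizes[sizes >= 4 & sizes <= n]
  fl <- vapply(sizes, function(l) {
    step <- max(1, floor(l / 2))
    starts <- seq(1, n - l + 1, by = step)
    t <- seq_len(l)
    X <- cbind(1, t)
    sds <- vapply(starts, function(s) {
      w <- x[s:(s + l - 1)]
      r <- stats::lm.fit(X, w)$residuals
      sqrt(mean(r^2))
    }, numeric(1))
    mean(sds)
  }, numeric(1))
  infit <- sizes >= fit_range_s[1] * fs & sizes <= fit_range_s[2] * fs
  unname(coef(lm(log(fl[infit]) ~ log(sizes[infit])))[2])
}

# tiny constructed feature table for PCA-stage tests
toy_feature_table <- function(n_frag = 6, channels = c("Fz", "Cz", "Pz"),
                              seed = 42) {
  set.seed(seed)
  keys <- expand.grid(
    fragment_id = sprintf("F%02d", seq_len(n_frag)),
    channel = channels, stringsAsFactors = FALSE
  )
  keys$participant <- rep(c("P01", "P02"), length.out = nrow(keys))
  keys$task <- "LA"
  keys$background <- rep(c("PK", "MT"), length.out = nrow(keys))
  keys$topic <- "T01"
  n <- nrow(keys)
  cbind(keys, data.frame(
    AP_alpha = exp(rnorm(n)), RP_alpha = runif(n),
    SEV1 = runif(n, 0.5, 1), CF_alpha = runif(n, 9, 11)
  ))
}

toy_registry <- function() {
  data.frame(name = c("AP_alpha", "RP_alpha", "SEV1", "CF_alpha"),
             log_transform = c(TRUE, FALSE, FALSE, FALSE))
}
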