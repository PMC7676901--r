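#' Alpha peak frequency and power by root-MUSIC
#'
#' Subspace spectral-line estimation: the signal is band-pass filtered
#' (order-2 Butterworth), its autocorrelation matrix over `n_lags` lags
#' is eigendecomposed, and the noise-subspace polynomial is rooted. The
#' in-band root closest to the unit circle gives the peak frequency MF;
#' its power MP (uV^2) is recovered from the signal-subspace eigenvalues
#' by a least-squares fit of the line-power model.
#'
#' @param x Single-channel samples.
#' @param fs Sampling rate (Hz).
#' @param band Analysis band, `c(7, 13)` or `c(8, 13)` conventionally.
#' @param P Signal-subspace dimension (complex exponentials); `P = 2`
#'   models one real spectral line.
#' @param n_lags Autocorrelation order (matrix size). Kept at 64 by
#'   default; much larger values make the degree-`2(n_lags-1)` noise
#'   polynomial numerically fragile to root.
#' @param filter_order Butterworth order of the band-pass.
#' @return List with `MF` (Hz), `MP` (uV^2), `in_band` (FALSE when no
#'   noise-subspace root fell inside the band and the nearest root was
#'   projected onto the band edge), `band`, and `P`.
#' @export
rootmusic_peak <- function(x, fs, band = c(8, 13), P = 2, n_lags = 64,
                           filter_order = 2) {
  if (sd(x) == 0) stop("constant input")
  M <- n_lags
  if (M < 2 * P + 1) stop("n_lags must be at least 2P + 1")
  if (length(x) < 4 * M) stop("signal too short for autocorrelation order")
  bf <- signal::butter(filter_order, band / (fs / 2), type = "pass")
  xf <- signal::filtfilt(bf, x)
  ac <- acf(xf, lag.max = M - 1, type = "covariance", plot = FALSE,
            demean = TRUE)$acf[, 1, 1]
  eg <- eigen(toeplitz(ac), symmetric = TRUE)
  En <- eg$vectors[, (P + 1):M, drop = FALSE]
  Cn <- tcrossprod(En)
  # noise polynomial coefficients = anti-diagonal sums of the projector
  d <- vapply(-(M - 1):(M - 1), function(k) {
    sum(Cn[row(Cn) - col(Cn) == k])
  }, numeric(1))
  r <- polyroot(rev(d))
  r <- r[Mod(r) <= 1 + 1e-9 & Im(r) > 0] # positive-frequency half plane
  if (length(r) == 0) stop("no roots found; input may be rank deficient")
  fr <- Arg(r) / (2 * pi) * fs
  inband <- fr >= band[1] & fr <= band[2]
  flagged <- !any(inband)
  if (flagged) {
    # no in-band root: project the nearest root onto the band
    near <- which.min(pmin(abs(fr - band[1]), abs(fr - band[2])))
    mf <- min(max(fr[near], band[1]), band[2])
    root_sel <- r[near]
  } else {
    rin <- r[inband]
    fin <- fr[inband]
    pick <- order(abs(Mod(rin) - 1))[1]
    mf <- fin[pick]
    root_sel <- rin[pick]
  }
  # line power from the signal-subspace eigenvalues:
  # lambda_k - sigma^2 = sum_i P_i |v_k^H a(f_i)|^2
  sigma2 <- mean(eg$values[(P + 1):M])
  a_vec <- exp(1i * 2 * pi * mf / fs * (0:(M - 1)))
  Vs <- eg$vectors[, seq_len(P), drop = FALSE]
  proj <- Mod(crossprod(Vs, a_vec))^2 # |v_k^H a|^2, real signal: conj pair shares
  lam <- pmax(eg$values[seq_len(P)] - sigma2, 0)
  denom <- sum(proj^2)
  mp <- if (denom > 0) sum(proj * lam) / denom * 2 else 0 # x2: conjugate line
  list(MF = unname(mf), MP = unname(mp), in_band = !flagged,
       band = band, P = P)
}

#' Welch PSD at 0.1 Hz resolution for alpha-peak fitting
#'
#' Convenience wrapper: 10 s Hamming windows with 5 s overlap and an FFT
#' length of exactly `10 * fs`, giving a 0.1 Hz grid.
#'
#' @param x Single-channel samples (at least 10 s).
#' @param fs Sampling rate (Hz).
#' @return A `psd_estimate` on a 0.1 Hz grid.
#' @export
psd_fine <- function(x, fs) {
  welch_psd(x, fs, window_s = 10, overlap_s = 5, nfft = round(10 * fs))
}

find_local_maxima <- function(y) which(diff(sign(diff(y))) == -2) + 1

#' Individual alpha frequency via 1/f-detrended Gaussian fit
#'
#' Procedure: (i) locate local PSD maxima in the alpha search band; (ii)
#' fit a line `y0 = p1*f + p2` to `ln(p)` over the fit range and remove
#' the implied `1/f` background `z = exp(p2 + f*p1)` giving the
#' detrended spectrum `s = p - z`; (iii) fit a single Gaussian
#' `a1*exp(-((f-b1)/c1)^2)` to `s`; (iv) accept the peak if its total
#' height `a1 + z(b1)` exceeds the upper 95% prediction bound of the
#' background fit at `b1` (evaluated on the linear-power scale, which
#' makes the decision invariant to rescaling the PSD); (v) delimit the
#' individual alpha interval `[f1, f2]` with `f1 = TF`, the
#' minimum-power (transition) frequency between `tf_lower` and the peak,
#' and `f2 = |5 - (f_alpha - 1)| + f_alpha`; (vi) compute the center of
#' gravity `IAF = sum(f*p)/sum(p)` over `[f1, f2]`; (vii) update `f2`
#' from the obtained IAF and recompute the center of gravity once.
#'
#' @param psd A `psd_estimate` covering at least 1-20 Hz at a grid
#'   spacing of 0.1 Hz or finer (see [psd_fine()]).
#' @param alpha_band Search band for the peak (Hz).
#' @param fit_range Frequency range of the 1/f background fit (Hz).
#' @param tf_lower Lower bound of the transition-frequency search (Hz).
#' @return List with `accepted`, `IAF`, `f_alpha` (Gaussian center),
#'   `p_alpha` (Gaussian amplitude), `TF`, `fit_interval` = `c(f1, f2)`.
#'   When no acceptable peak exists, `accepted = FALSE` and `IAF = NA`.
#' @export
fit_iaf <- function(psd, alpha_band = c(8, 13), fit_range = c(1, 45),
                    tf_lower = 4) {
  df <- psd$freq[2] - psd$freq[1]
  if (df > 0.1 + 1e-9) stop("PSD grid coarser than 0.1 Hz")
  if (max(psd$freq) < 20 || min(psd$freq) > 1) stop("PSD must cover 1-20 Hz")
  rej <- function(f_alpha = NA_real_) {
    list(accepted = FALSE, IAF = NA_real_, f_alpha = f_alpha,
         p_alpha = NA_real_, TF = NA_real_, fit_interval = c(NA_real_, NA_real_))
  }
  sel <- psd$freq >= fit_range[1] & psd$freq <= min(fit_range[2], max(psd$freq))
  f0 <- psd$freq[sel]
  p0 <- psd$power[sel]
  if (any(p0 <= 0)) p0 <- pmax(p0, .Machine$double.xmin)
  ia <- f0 >= alpha_band[1] & f0 <= alpha_band[2]
  pk <- find_local_maxima(p0)
  pk <- pk[ia[pk]]
  if (length(pk) == 0) return(rej())
  bg <- lm(lp ~ f0, data = data.frame(f0 = f0, lp = log(p0)))
  z <- exp(predict(bg))
  s <- p0 - z
  st <- list(a1 = max(s[ia]), b1 = f0[ia][which.max(s[ia])], c1 = 1)
  fit <- try(
    minpack.lm::nlsLM(s ~ a1 * exp(-((f0 - b1) / c1)^2),
                      data = data.frame(f0 = f0, s = s), start = st,
                      lower = c(0, 7, 0.05), upper = c(Inf, 14, 5),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    silent = TRUE
  )
  if (inherits(fit, "try-error")) return(rej())
  cf <- coef(fit)
  f_alpha <- unname(cf["b1"])
  a1 <- unname(cf["a1"])
  zb <- exp(predict(bg, newdata = data.frame(f0 = f_alpha),
                    interval = "prediction"))
  if (!(a1 + zb[1, "fit"] > zb[1, "upr"])) return(rej(f_alpha))
  tfsel <- f0 >= tf_lower & f0 <= f_alpha
  TF <- f0[tfsel][which.min(p0[tfsel])]
  cog <- function(f1, f2) {
    s2 <- f0 >= f1 & f0 <= f2
    sum(f0[s2] * p0[s2]) / sum(p0[s2])
  }
  f1 <- TF
  f2 <- abs(5 - (f_alpha - 1)) + f_alpha
  iaf <- cog(f1, f2)
  f2 <- abs(5 - (iaf - 1)) + iaf
  iaf <- cog(f1, f2)
  list(accepted = TRUE, IAF = iaf, f_alpha = f_alpha, p_alpha = a1,
       TF = TF, fit_interval = c(f1, f2))
}
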