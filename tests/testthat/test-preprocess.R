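make_rec <- function(n_ch = 4, n = 512, fs = 128, seed = 1) {
  set.seed(seed)
  eeg_recording(matrix(rnorm(n_ch * n), n_ch), fs,
                labels = c("Fz", "Cz", "Pz", "Oz")[seq_len(n_ch)])
}

test_that("re-referencing is idempotent, zeroes the reference, and keeps contrasts", {
  rec <- make_rec()
  r1 <- rereference(rec, "Cz")
  r2 <- rereference(r1, "Cz")
  expect_equal(r1$data, r2$data)
  expect_true(all(r1$data["Cz", ] == 0))
  expect_equal(r1$data["Pz", ] - r1$data["Fz", ],
               rec$data["Pz", ] - rec$data["Fz", ])
  expect_identical(r1$reference, "Cz")
  expect_error(rereference(rec, "nose"), "not found")
})

test_that("band-pass filter preserves the pass band and removes DC and drift", {
  # realized response of the canonical design: order 3380 at 512 Hz
  fs0 <- 512
  b0 <- as.numeric(signal::fir1(3380, c(0.5, 134) / (fs0 / 2), type = "pass",
                                window = signal::hamming(3381)))
  H0 <- function(f) abs(sum(b0 * exp(-1i * 2 * pi * f * seq_along(b0) / fs0)))
  expect_lt(20 * log10(H0(0.05)), -20) # slow drift attenuated >= 20 dB
  expect_lt(H0(0), 0.01)               # DC removed to < 1%
  # pass-band ripple < 1 dB between 1 and 100 Hz
  ripple <- vapply(c(1, 2, 5, 10, 25, 50, 75, 100), H0, numeric(1))
  expect_true(all(abs(20 * log10(ripple)) < 1))
  # applied zero-phase to a 10 Hz tone: amplitude preserved, no phase shift
  fs <- 128
  t <- seq(0, 20, by = 1 / fs)[-1]
  ord <- 400
  x <- sin(2 * pi * 10 * t)
  rec <- eeg_recording(rbind(x, x), fs, labels = c("Fz", "Cz"))
  out <- resample_filter(rec, target_fs = fs, band = c(0.5, 45), order = ord)
  mid <- (5 * fs):(15 * fs)
  expect_equal(out$data[1, mid], x[mid], tolerance = 0.02)
  # applied DC suppression matches the short filter's realized response
  b1 <- as.numeric(signal::fir1(ord, c(0.5, 45) / (fs / 2), type = "pass",
                                window = signal::hamming(ord + 1)))
  H1_0 <- abs(sum(b1))
  recdc <- eeg_recording(matrix(rep(1, length(t)), 1), fs, labels = "Fz")
  outdc <- resample_filter(recdc, fs, c(0.5, 45), ord)
  expect_equal(mean(outdc$data[1, mid]), H1_0, tolerance = 0.005)
  expect_error(resample_filter(rec, fs, c(0.5, 70), ord), "Nyquist")
})

test_that("filtering is linear and resampling halves the rate", {
  fs <- 256
  set.seed(2)
  x <- rnorm(fs * 4)
  y <- rnorm(fs * 4)
  rec_x <- eeg_recording(matrix(x, 1), fs, "Fz")
  rec_y <- eeg_recording(matrix(y, 1), fs, "Fz")
  rec_mix <- eeg_recording(matrix(2 * x + 3 * y, 1), fs, "Fz")
  f <- function(r) resample_filter(r, 128, c(0.5, 45), 200)$data[1, ]
  expect_equal(f(rec_mix), 2 * f(rec_x) + 3 * f(rec_y), tolerance = 1e-9)
  expect_equal(length(f(rec_x)), fs * 4 / 2)
})

test_that("delay estimation recovers shifts with sign and tie conventions", {
  set.seed(3)
  audio <- as.numeric(signal::filtfilt(signal::butter(4, 0.5), rnorm(4000)))
  shifted <- c(rep(0, 100), audio)[1:4000]
  expect_equal(estimate_delay(shifted, audio), 100)
  # audio leading the recording: negative lag
  lead <- c(audio[51:4000], rep(0, 50))
  expect_equal(estimate_delay(lead, audio), -50)
  expect_equal(estimate_delay(audio, audio), 0)
  expect_error(estimate_delay(rep(1, 100), audio), "constant")
})

test_that("fragment splitting is exact and invertible", {
  fs <- 128
  rec <- make_rec(n = 10 * fs, fs = fs)
  man <- data.frame(participant = "P01", task = c("BA", "BUA"),
                    background = "MT", start_s = c(0, 4), stop_s = c(4, 8))
  fr <- split_fragments(rec, man)
  expect_length(fr, 2)
  expect_equal(ncol(fr[[1]]$recording$data), 4 * fs)
  expect_identical(fr[[1]]$tags$task, "BA")
  # concatenating contiguous fragments reproduces the spanned signal
  expect_equal(cbind(fr[[1]]$recording$data, fr[[2]]$recording$data),
               rec$data[, 1:(8 * fs)])
  expect_length(split_fragments(rec, man[0, ]), 0)
  expect_error(split_fragments(rec, transform(man, stop_s = c(4, 99))),
               "out of range")
  expect_error(
    split_fragments(rec, data.frame(start_s = c(0, 2), stop_s = c(4, 6))),
    "overlap"
  )
})

test_that("subregion map partitions the full montage into six groups", {
  labels <- scalp_labels(64)
  expect_length(labels, 64)
  expect_false(anyDuplicated(labels) > 0)
  map <- subregion_map(labels)
  expect_setequal(unique(map),
                  c("frontal", "central", "left_temporal", "right_temporal",
                    "parietal", "occipital"))
  expect_length(map, 64) # every channel in exactly one subregion
  expect_true(all(table(map) > 0))
  # reduced montages still cover all six subregions
  expect_length(unique(subregion_map(scalp_labels(6))), 6)
  expect_error(subregion_map(c("Fz", "XX9")), "unmapped")
})

test_that("EDF round-trip preserves signals to quantization accuracy", {
  set.seed(4)
  rec <- eeg_recording(matrix(rnorm(3 * 256, sd = 20), 3), fs = 128,
                       labels = c("Fz", "Cz", "Pz"))
  path <- tempfile(fileext = ".edf")
  write_edf(rec, path)
  back <- read_edf(path)
  expect_identical(back$labels, rec$labels)
  expect_equal(back$fs, rec$fs)
  rng <- apply(rec$data, 1, function(r) diff(range(r)))
  expect_lt(max(abs(back$data - rec$data)), max(rng) / 65535 * 2)
  unlink(path)
})
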