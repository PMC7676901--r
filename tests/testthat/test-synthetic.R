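test_that("fGn generator produces the requested Hurst exponent and rejects bad H", {
  expect_error(fgn_sim(100, 0), "inside")
  expect_error(fgn_sim(100, 1), "inside")
  set.seed(1)
  # white-noise case: lag-1 autocorrelation should vanish
  x <- fgn_sim(2^14, 0.5)
  expect_lt(abs(cor(x[-1], x[-length(x)])), 0.03)
  # H = 0.8: theoretical lag-1 autocorrelation 2^(2H-1) - 1
  y <- fgn_sim(2^15, 0.8)
  rho1 <- 2^(2 * 0.8 - 1) - 1
  expect_lt(abs(cor(y[-1], y[-length(y)]) - rho1), 0.05)
  # independent DFA oracle on the raw fGn recovers H (module invariant)
  set.seed(2)
  sev <- mean(replicate(5, oracle_dfa_sev(fgn_sim(512 * 120, 0.7), 512,
                                          fit_range_s = c(2.5, 15))))
  expect_lt(abs(sev - 0.7), 0.05)
})

test_that("1/f background has the planted log-PSD slope", {
  set.seed(3)
  # white background: slope ~ 0
  x <- onef_noise(256 * 120, 0, 256)
  psd <- welch_psd(x, 256, nfft = 4096)
  sel <- psd$freq >= 2 & psd$freq <= 60
  sl <- coef(lm(log(psd$power[sel]) ~ log(psd$freq[sel])))[2]
  expect_lt(abs(sl), 0.05)
  # pink-ish background: slope ~ -1
  y <- onef_noise(256 * 120, 1, 256)
  psd2 <- welch_psd(y, 256, nfft = 4096)
  sl2 <- coef(lm(log(psd2$power[sel]) ~ log(psd2$freq[sel])))[2]
  expect_lt(abs(sl2 + 1), 0.1)
})

test_that("generate_recording plants a spectral bump and a recoverable envelope", {
  set.seed(4)
  osc <- oscillator_spec(10, peak_power = 6, bandwidth_hz = 1,
                         envelope_hurst = 0.5)
  g <- generate_recording(60, 256, n_channels = 1, oscillators = osc,
                          onef_exponent = 0, background_sd = 0.5)
  x <- g$recording$data[1, ]
  psd <- welch_psd(x, 256, nfft = 4096)
  sel <- psd$freq >= 2 & psd$freq <= 45
  expect_equal(psd$freq[sel][which.max(psd$power[sel])], 10, tolerance = 0.5)
  # ground truth stores the planted values
  expect_equal(g$truth$oscillators[[1]]$center_hz, 10)
  expect_equal(g$truth$oscillators[[1]]$envelope_hurst, 0.5)
  expect_length(g$truth$oscillators[[1]]$envelope_fgn, 60 * 256)
  # oscillator rejects out-of-range parameters
  expect_error(oscillator_spec(10, envelope_hurst = 1.2), "inside")
  expect_error(generate_recording(10, 256, 1,
                                  oscillators = oscillator_spec(200)),
               "Nyquist")
})

test_that("recording generation is reproducible from (spec, seed)", {
  osc <- oscillator_spec(10)
  a <- generate_recording(5, 128, n_channels = 2, oscillators = osc, seed = 7)
  b <- generate_recording(5, 128, n_channels = 2, oscillators = osc, seed = 7)
  expect_identical(a$recording$data, b$recording$data)
})

test_that("sync channel stores an exact delayed copy and validates the delay", {
  rec <- eeg_recording(matrix(rnorm(200), 1), fs = 100, labels = "Cz")
  audio <- sin(2 * pi * 3 * seq(0, 1.99, by = 0.01))
  out <- generate_sync_channel(rec, audio, delay_samples = 30)
  expect_equal(unname(out$data["Sound", 31:200]), audio[1:170])
  expect_equal(attr(out, "sync_delay"), 30)
  expect_error(generate_sync_channel(rec, audio, 200), "delay")
  expect_error(generate_sync_channel(rec, audio, -1), "delay")
})

test_that("cohort layout covers all conditions and rotates topics through silence", {
  spec <- cohort_spec(8, fs = 128, n_channels = 6,
                      fragment_duration_s = c(LA = 10, BA = 8, BUA = 8),
                      seed = 5)
  osc <- oscillator_spec(10)
  co <- simulate_cohort(spec, osc)
  man <- co$manifest
  # ten conditions: LA x 4 backgrounds + BA/BUA x 3 noise backgrounds
  cells <- unique(man[, c("task", "background")])
  expect_equal(nrow(cells), 10)
  expect_false(any(cells$background == "PK" & cells$task != "LA"))
  # every LA fragment has a topic; each topic reaches pink noise >= 2 times
  la <- man[man$task == "LA", ]
  expect_false(anyNA(la$topic))
  pk <- table(la$topic[la$background == "PK"])
  expect_true(all(pk >= 2))
  # fragments are non-overlapping and ordered per participant
  for (p in unique(man$participant)) {
    m <- man[man$participant == p, ]
    expect_true(all(m$start_s[-1] >= m$stop_s[-nrow(m)]))
  }
  # identical spec + seed is bit-identical
  co2 <- simulate_cohort(spec, osc)
  expect_identical(co$truth, co2$truth)
})

test_that("exam scores respond to planted latent weights and degenerate plans are flagged", {
  spec <- cohort_spec(10, tasks = "LA", fs = 128, n_channels = 6,
                      fragment_duration_s = c(LA = 10), seed = 6)
  osc <- oscillator_spec(10, envelope_hurst = 0.7)
  plan <- effect_plan(
    participant_sd = c(envelope_hurst = 0.1),
    fragment_sd = c(envelope_hurst = 0.05),
    exam_weights = c(envelope_hurst = -4),
    exam_noise_sd = 0.3, exam_participant_sd = 0
  )
  co <- simulate_cohort(spec, osc, plan)
  exam <- generate_exam_table(co)
  # strong planted negative weight shows up as a negative raw correlation
  expect_lt(cor(exam$keywords_correct, exam$latent_envelope_hurst), -0.5)
  # all-zero weights and zero noise give constant scores -> degenerate
  plan0 <- effect_plan(participant_sd = c(envelope_hurst = 0),
                       fragment_sd = c(envelope_hurst = 0),
                       exam_noise_sd = 0, exam_participant_sd = 0)
  co0 <- simulate_cohort(spec, osc, plan0)
  exam0 <- generate_exam_table(co0)
  expect_true(all(exam0$keywords_correct == exam0$keywords_correct[1]))
  ez <- exam_zscores(exam0)
  expect_true(all(attr(ez, "pink_stats")$degenerate))
  expect_true(all(is.na(ez$z)))
})
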