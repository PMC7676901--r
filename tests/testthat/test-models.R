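sim_lmm_data <- function(n_p = 12, n_obs = 12, beta_la = 0.5, sd_u = 0.3,
                         sd_e = 0.5) {
  pid <- rep(sprintf("P%02d", seq_len(n_p)), each = n_obs)
  task <- rep_len(c("BA", "BUA", "LA"), n_p * n_obs)
  u <- rnorm(n_p, sd = sd_u)
  names(u) <- unique(pid)
  data.frame(participant = pid, task = task,
             y = 1 + beta_la * (task == "LA") + u[pid] + rnorm(n_p * n_obs, sd = sd_e))
}

test_that("model fits satisfy the AIC identity and expose variance components", {
  set.seed(1)
  dat <- sim_lmm_data()
  fit <- fit_lmm(y ~ task + (1 | participant), dat)
  expect_equal(fit$AIC, -2 * fit$logLik + 2 * fit$edf, tolerance = 1e-12)
  expect_true(fit$mixed)
  expect_named(fit$ranef_var, "participant")
  # edf counts fixed coefficients + variance components + residual
  expect_equal(fit$edf, 3 + 1 + 1)
  # fixed-only dispatch
  flm <- fit_lmm(y ~ task, dat)
  expect_false(flm$mixed)
  expect_equal(flm$AIC, AIC(flm$model), tolerance = 1e-10)
  # fitted + residuals = response
  expect_equal(unname(fitted(flm$model) + residuals(flm$model)), dat$y,
               tolerance = 1e-10)
})

test_that("planted zero between-participant variance yields a flagged near-zero estimate", {
  set.seed(2)
  dat <- sim_lmm_data(sd_u = 0)
  fit <- fit_lmm(y ~ task + (1 | participant), dat)
  expect_lt(unname(fit$ranef_var["participant"]), 0.01)
})

test_that("Tukey tables separate well-separated groups and keep direction bookkeeping", {
  set.seed(3)
  dat <- sim_lmm_data(n_p = 10, beta_la = 0)
  dat$y <- dat$y + 5 * 0.5 * (dat$task == "LA") # 5 pooled SDs apart
  fit <- fit_lmm(y ~ task + (1 | participant), dat)
  tk <- tukey_posthoc(fit, "task", dat)
  la_pair <- tk$comparisons[tk$comparisons$level_a == "LA" |
                              tk$comparisons$level_b == "LA", ]
  expect_true(all(la_pair$p_adj < 0.001))
  expect_identical(tk$argmax, "LA")
  # direction is the sign of the estimate, and estimates match marginal means
  em <- tk$marginal_means
  for (i in seq_len(nrow(tk$comparisons))) {
    a <- tk$comparisons$level_a[i]
    b <- tk$comparisons$level_b[i]
    expect_equal(tk$comparisons$estimate[i], unname(em[a] - em[b]),
                 tolerance = 1e-6)
  }
  expect_error(tukey_posthoc(fit, "task",
                             transform(dat, task = "LA")), "levels")
})

test_that("exam z-scores follow the silence-referenced formula exactly", {
  exam <- data.frame(
    participant = c("P01", "P02", "P01", "P02"),
    topic = "T01",
    background = c("PK", "PK", "MT", "MT"),
    keywords_correct = c(3, 5, 5, 2)
  )
  ez <- exam_zscores(exam)
  st <- attr(ez, "pink_stats")
  expect_equal(st$mu_pink, 4)
  expect_equal(st$sigma_pink, sd(c(3, 5)))
  # hand-checked case: mu = 3, sigma = 2 -> (5 - 3) / 2 = 1
  exam2 <- data.frame(participant = c("P01", "P02", "P03"), topic = "T01",
                      background = c("PK", "PK", "MT"),
                      keywords_correct = c(3 - 2 / sqrt(2) * 1, 3 + 2 / sqrt(2) * 1, 5))
  # construct pink rows with mean 3, sd 2
  exam2$keywords_correct[1:2] <- c(3 - sqrt(2), 3 + sqrt(2))
  ez2 <- exam_zscores(exam2)
  expect_equal(attr(ez2, "pink_stats")$mu_pink, 3)
  expect_equal(attr(ez2, "pink_stats")$sigma_pink, 2)
  expect_equal(ez2$z[3], 1)
  # pink rows of each topic standardize to mean 0, sd 1 by construction
  expect_equal(mean(ez2$z[1:2]), 0, tolerance = 1e-12)
  expect_equal(sd(ez2$z[1:2]), 1, tolerance = 1e-12)
  # permuting participants leaves z unchanged
  perm <- exam[c(2, 1, 4, 3), ]
  expect_equal(sort(exam_zscores(perm)$z), sort(ez$z))
  expect_error(exam_zscores(exam[-1, ]), "fewer than 2")
})

test_that("backward elimination removes noise terms and keeps strong ones", {
  set.seed(4)
  n <- 300
  dat <- data.frame(x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n))
  dat$y <- 1 + 2 * dat$x1 + 1.5 * dat$x2 + rnorm(n)
  full <- fit_lmm(y ~ x1 + x2 + x3, dat)
  sw <- stepwise_backward(full, dat)
  expect_true(all(c("x1", "x2") %in% sw$retained))
  expect_false("x3" %in% sw$retained)
  # agrees with the standard step() backward reduction for lm
  ref <- stats::step(lm(y ~ x1 + x2 + x3, dat), direction = "backward",
                     trace = 0)
  expect_setequal(sw$retained, attr(terms(ref), "term.labels"))
  # all-strong predictors: nothing is eliminated
  dat2 <- dat
  dat2$y <- 1 + 2 * dat2$x1 + 2 * dat2$x2 + 2 * dat2$x3 + rnorm(n, sd = 0.5)
  sw2 <- stepwise_backward(fit_lmm(y ~ x1 + x2 + x3, dat2), dat2)
  expect_setequal(sw2$retained, c("x1", "x2", "x3"))
})

test_that("model comparison reports exact LRT and AIC arithmetic", {
  set.seed(5)
  dat <- sim_lmm_data()
  f0 <- fit_lmm(y ~ 1 + (1 | participant), dat)
  f1 <- fit_lmm(y ~ task + (1 | participant), dat)
  cmp <- compare_models(f0, f1)
  expect_true(cmp$nested)
  expect_equal(cmp$chisq, 2 * (f1$logLik - f0$logLik), tolerance = 1e-10)
  expect_equal(cmp$df, f1$edf - f0$edf)
  expect_equal(cmp$delta_aic,
               (-2 * f1$logLik + 2 * f1$edf) - (-2 * f0$logLik + 2 * f0$edf),
               tolerance = 1e-10)
  # identical models: chisq 0, p 1
  cmp0 <- compare_models(f0, f0)
  expect_equal(cmp0$chisq, 0)
  expect_equal(cmp0$p_value, 1)
  # logLik -10, edf 3 -> AIC 26 exactly
  expect_equal(-2 * -10 + 2 * 3, 26)
  # non-nested models refuse the LRT
  fa <- fit_lmm(y ~ task, dat)
  fb <- fit_lmm(y ~ participant, dat)
  cmp2 <- compare_models(fa, fb)
  expect_false(cmp2$nested)
  expect_true(is.na(cmp2$p_value))
})

test_that("within-condition wrappers produce one fit and Tukey table per cell", {
  set.seed(6)
  n_p <- 6
  grid <- expand.grid(
    participant = sprintf("P%02d", 1:n_p),
    task = c("LA", "BA", "BUA"),
    background = c("PK", "MT", "HW", "FT"),
    subregion = c("frontal", "central", "parietal"),
    stringsAsFactors = FALSE
  )
  grid <- grid[!(grid$background == "PK" & grid$task != "LA"), ]
  for (pc in paste0("PC", 1:2)) grid[[pc]] <- rnorm(nrow(grid))
  wt <- within_condition_models(grid, within = "task", k = 2)
  expect_named(wt, c("BA", "BUA", "LA"))
  expect_named(wt$LA, c("PC1", "PC2"))
  expect_s3_class(wt$LA$PC1$tukey, "tukey_table")
  # within-background: PK has a single task level and is skipped
  wb <- within_condition_models(grid, within = "background", k = 2)
  expect_false("PK" %in% names(wb))
  expect_length(wb, 3)
})

test_that("exam prediction recovers a planted single-predictor model", {
  set.seed(7)
  # construct subregion scores directly with a planted parietal PC2 effect
  n_p <- 12
  subs <- c("frontal", "central", "left_temporal", "right_temporal",
            "parietal", "occipital")
  rows <- expand.grid(participant = sprintf("P%02d", 1:n_p),
                      topic = sprintf("T%02d", 1:4),
                      subregion = subs, stringsAsFactors = FALSE)
  rows$background <- c(PK = "PK", MT = "MT", HW = "HW", FT = "FT")[
    (as.integer(factor(rows$topic)) - 1) %% 4 + 1]
  rows$task <- "LA"
  rows$fragment_id <- paste0(rows$participant, rows$topic)
  for (pc in paste0("PC", 1:3)) rows[[pc]] <- rnorm(nrow(rows))
  wide_key <- unique(rows[, c("participant", "topic", "background")])
  par_pc2 <- rows$PC2[rows$subregion == "parietal"]
  names(par_pc2) <- rows$fragment_id[rows$subregion == "parietal"]
  examz <- wide_key
  examz$keywords_correct <- 10
  examz$z <- -0.8 * par_pc2[paste0(examz$participant, examz$topic)] +
    rnorm(nrow(examz), sd = 0.3)
  pe <- predict_exam(examz, rows, mode = "fixed", k = 3)
  expect_true("PC2_parietal" %in% pe$stepwise$retained)
  cf <- pe$fits$eeg_stepwise$coefficients
  expect_lt(cf$estimate[cf$term == "PC2_parietal"], 0)
  expect_lt(pe$aic["eeg_stepwise"], pe$aic["background"])
  expect_lt(pe$comparisons$eeg_stepwise_vs_constant$p_value, 0.01)
})
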