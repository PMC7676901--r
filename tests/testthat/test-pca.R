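test_that("matrix assembly applies the log rule and z-scores with sample SD", {
  ft <- toy_feature_table()
  reg <- toy_registry()
  fm <- build_matrix(ft, reg)
  expect_equal(unname(colMeans(fm$X)), rep(0, 4), tolerance = 1e-10)
  expect_equal(unname(apply(fm$X, 2, sd)), rep(1, 4), tolerance = 1e-10)
  # AP column {e^1, e^3} post-log z-scores equal those of {1, 3}
  ft2 <- ft[1:2, ]
  ft2$AP_alpha <- exp(c(1, 3))
  ft2$RP_alpha <- c(0.2, 0.4)
  ft2$SEV1 <- c(0.6, 0.8)
  ft2$CF_alpha <- c(9, 11)
  fm2 <- build_matrix(ft2, reg)
  expect_equal(unname(fm2$X[, "AP_alpha"]), c(-1, 1) / sqrt(2), tolerance = 1e-12)
  # errors: non-positive powers, constant columns
  ft3 <- ft
  ft3$AP_alpha[1] <- 0
  expect_error(build_matrix(ft3, reg), "non-positive")
  ft4 <- ft
  ft4$CF_alpha <- 10
  expect_error(build_matrix(ft4, reg), "constant")
  # channel exclusions drop rows before normalization
  fm5 <- build_matrix(ft, reg, exclude_channels = "Pz")
  expect_false(any(fm5$keys$channel == "Pz"))
})

test_that("SVD identities hold and match the covariance-eigendecomposition oracle", {
  set.seed(1)
  n <- 80
  p <- 6
  ft <- data.frame(matrix(rnorm(n * p), n))
  names(ft) <- sprintf("F%d", 1:p)
  ft$channel <- "Cz"
  reg <- data.frame(name = sprintf("F%d", 1:p), log_transform = FALSE)
  fm <- build_matrix(ft, reg)
  pc <- fit_pca(fm)
  V <- pc$loadings
  expect_equal(t(V) %*% V, diag(p), tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(pc$scores, fm$X %*% V, tolerance = 1e-10)
  expect_equal(fm$X,
               pc$scores %*% t(V), tolerance = 1e-8) # X = (US)V'
  expect_equal(sum(pc$explained_var), 1, tolerance = 1e-12)
  expect_equal(unname(colSums(pc$contributions)), rep(100, p), tolerance = 1e-8)
  # oracle: eigenvalues of X'X/(n-1) give identical explained variance
  ev <- eigen(crossprod(fm$X) / (n - 1), symmetric = TRUE)$values
  expect_equal(pc$explained_var, ev / sum(ev), tolerance = 1e-8)
  # sign convention: largest-magnitude loading positive
  for (j in 1:p) expect_gt(V[which.max(abs(V[, j])), j], 0)
  # cumulative explained variance is monotone
  expect_true(all(diff(cumsum(pc$explained_var)) >= -1e-14))
})

test_that("planted one-dimensional structure dominates the first component", {
  set.seed(2)
  n <- 200
  p <- 8
  u <- rnorm(n)
  X <- outer(u, rnorm(p)) + matrix(rnorm(n * p, sd = 0.1), n)
  ft <- as.data.frame(X)
  names(ft) <- sprintf("F%d", 1:p)
  ft$channel <- "Cz"
  reg <- data.frame(name = sprintf("F%d", 1:p), log_transform = FALSE)
  pc <- fit_pca(build_matrix(ft, reg))
  expect_gt(pc$explained_var[1], 0.9)
})

test_that("subregion averaging is a plain mean of raw scores in the paper's order", {
  ft <- toy_feature_table(n_frag = 2, channels = c("Fz", "F3", "Cz"))
  reg <- toy_registry()
  pc <- fit_pca(build_matrix(ft, reg))
  map <- subregion_map(c("Fz", "F3", "Cz"))
  ss <- subregion_scores(pc, map, k = 2)
  cs <- channel_scores(pc, k = 2, map = map)
  for (fid in unique(ss$fragment_id)) {
    manual <- mean(cs$PC1[cs$fragment_id == fid & cs$subregion == "frontal"])
    expect_equal(ss$PC1[ss$fragment_id == fid & ss$subregion == "frontal"],
                 manual, tolerance = 1e-12)
  }
  # two channels with scores {1, 3} average to 2
  fake <- cs[cs$fragment_id == cs$fragment_id[1] & cs$subregion == "frontal", ]
  expect_equal(nrow(fake), 2)
})

test_that("LRTC contribution ranks components loaded on the scaling exponents", {
  set.seed(3)
  n <- 100
  # the SEV pair is almost collinear while the spectral pair is only
  # loosely coupled, so after z-scoring the leading component is
  # unambiguously the fluctuation-driven one
  sev_latent <- rnorm(n)
  other <- rnorm(n)
  ft <- data.frame(
    SEV1 = sev_latent + rnorm(n, sd = 0.05),
    SEV2 = sev_latent + rnorm(n, sd = 0.05),
    RP_alpha = other + rnorm(n, sd = 1),
    CF_alpha = other + rnorm(n, sd = 1),
    channel = "Cz"
  )
  reg <- data.frame(name = c("SEV1", "SEV2", "RP_alpha", "CF_alpha"),
                    log_transform = FALSE)
  pc <- fit_pca(build_matrix(ft, reg))
  lc <- lrtc_contribution(pc)
  # the leading component is the (nearly collinear) SEV pair
  expect_gt(lc[["PC1"]], 90)
  expect_lt(lc[["PC2"]], 20)
})

test_that("topographic maps respect uniform and single-channel inputs", {
  labels <- scalp_labels(64)
  vals <- setNames(rep(2.5, 64), labels)
  g <- topomap(vals)
  expect_lt(diff(range(g, na.rm = TRUE)), 1e-9)
  # a single hot channel puts the map maximum at that channel's position
  vals2 <- setNames(numeric(64), labels)
  vals2["Oz"] <- 5
  g2 <- topomap(vals2, grid_n = 67)
  gx <- seq(-1, 1, length.out = 67)
  idx <- which(g2 == max(g2, na.rm = TRUE), arr.ind = TRUE)[1, ]
  pos <- electrode_positions(labels)
  oz <- pos[pos$label == "Oz", ]
  expect_lt(abs(gx[idx["col"]] - oz$x) + abs(gx[idx["row"]] - oz$y), 0.15)
  expect_error(topomap(vals[1:10]), "32")
})
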