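#' Assemble and normalize the feature matrix
#'
#' Takes a long-format feature table (rows keyed by participant,
#' fragment, condition and channel), applies the natural-log transform
#' to the power features flagged in the registry, and z-scores every
#' column (sample SD, n-1). Rows containing excluded channels are
#' dropped before normalization.
#'
#' @param feature_table Data frame from [cohort_features()] or of the
#'   same shape.
#' @param registry Feature registry used to pick and transform columns.
#' @param exclude_channels Optional character vector of channels to drop.
#' @return Object of class `feature_matrix`: list with the normalized
#'   matrix `X`, the key data frame `keys`, per-column `center` and
#'   `scale`, and the `registry`.
#' @export
build_matrix <- function(feature_table, registry = feature_registry(),
                         exclude_channels = NULL) {
  missing <- setdiff(registry$name, names(feature_table))
  if (length(missing) > 0) {
    stop("feature table lacks registry features: ", paste(missing, collapse = ", "))
  }
  ft <- feature_table
  if (!is.null(exclude_channels)) ft <- ft[!ft$channel %in% exclude_channels, ]
  keep <- stats::complete.cases(ft[, registry$name, drop = FALSE])
  ft <- ft[keep, ]
  X <- as.matrix(ft[, registry$name, drop = FALSE])
  for (j in seq_len(nrow(registry))) {
    if (registry$log_transform[j]) {
      if (any(X[, j] <= 0)) {
        stop("non-positive values in power feature ", registry$name[j],
             " cannot be log-transformed")
      }
      X[, j] <- log(X[, j])
    }
  }
  ctr <- colMeans(X)
  scl <- apply(X, 2, sd)
  if (any(scl == 0)) {
    stop("constant feature column(s): ",
         paste(registry$name[scl == 0], collapse = ", "))
  }
  X <- sweep(sweep(X, 2, ctr, "-"), 2, scl, "/")
  key_cols <- intersect(c("participant", "fragment_id", "task", "background",
                          "topic", "channel"), names(ft))
  structure(
    list(X = X, keys = ft[, key_cols, drop = FALSE],
         center = ctr, scale = scl, registry = registry),
    class = "feature_matrix"
  )
}

#' Principal component analysis of a normalized feature matrix
#'
#' Singular value decomposition `X = U S V'`. Scores are `X V = U S`;
#' the explained-variance fraction of component i is `s_i^2 / sum s^2`;
#' feature contributions are the squared feature-score correlations
#' normalized to sum to 100% within each component. Component signs are
#' fixed so each loading vector's largest-magnitude element is positive.
#'
#' @param fm A `feature_matrix` from [build_matrix()].
#' @return Object of class `eeg_pca`: list with `loadings` (p x p),
#'   `singular_values`, `scores` (n x p), `explained_var`,
#'   `contributions` (% per feature and PC), and `keys`.
#' @export
fit_pca <- function(fm) {
  X <- fm$X
  if (all(X == 0)) stop("degenerate (all-zero) feature matrix")
  sv <- svd(X)
  V <- sv$v
  U <- sv$u
  for (j in seq_len(ncol(V))) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) {
      V[, j] <- -V[, j]
      U[, j] <- -U[, j]
    }
  }
  scores <- X %*% V
  pcs <- paste0("PC", seq_len(ncol(V)))
  dimnames(V) <- list(colnames(X), pcs)
  colnames(scores) <- pcs
  expl <- sv$d^2 / sum(sv$d^2)
  contrib <- matrix(0, nrow = ncol(X), ncol = ncol(V),
                    dimnames = list(colnames(X), pcs))
  for (j in seq_len(ncol(V))) {
    if (sv$d[j] > 1e-12 * sv$d[1]) {
      co <- suppressWarnings(as.numeric(stats::cor(X, scores[, j])))
      co[is.na(co)] <- 0
      contrib[, j] <- co^2 / sum(co^2) * 100
    }
  }
  structure(
    list(loadings = V, singular_values = sv$d, scores = scores,
         explained_var = expl, contributions = contrib, keys = fm$keys),
    class = "eeg_pca"
  )
}

#' @export
print.eeg_pca <- function(x, ...) {
  k <- min(10, length(x$explained_var))
  cat(sprintf("<eeg_pca> %d observations x %d features\n",
              nrow(x$scores), ncol(x$loadings)))
  cat("cumulative explained variance:",
      paste0(round(cumsum(x$explained_var[seq_len(k)]) * 100, 1), "%",
             collapse = " "), "\n")
  invisible(x)
}

#' Channel-level component scores with condition keys
#'
#' @param pca An `eeg_pca`.
#' @param k Number of components to keep.
#' @return Data frame: key columns plus `PC1..PCk` and `subregion`.
#' @param map Named subregion map for the channels (see
#'   [subregion_map()]).
#' @export
channel_scores <- function(pca, k = 9, map = NULL) {
  out <- cbind(pca$keys, as.data.frame(pca$scores[, seq_len(k), drop = FALSE]))
  if (!is.null(map)) out$subregion <- unname(map[out$channel])
  rownames(out) <- NULL
  out
}

#' Subregion-averaged component scores
#'
#' Averages the channel-level PC scores (raw scores, averaged after
#' scoring -- never re-normalized) within each of the six scalp
#' subregions, per fragment.
#'
#' @param pca An `eeg_pca`.
#' @param map Named character vector mapping channels to subregions.
#' @param k Number of components to average.
#' @return Data frame keyed by the fragment keys plus `subregion`, with
#'   columns `PC1..PCk`.
#' @export
subregion_scores <- function(pca, map, k = 9) {
  cs <- channel_scores(pca, k = k, map = map)
  if (anyNA(cs$subregion)) stop("channels missing from the subregion map")
  key_cols <- intersect(c("participant", "fragment_id", "task", "background",
                          "topic"), names(cs))
  pcs <- paste0("PC", seq_len(k))
  agg <- aggregate(cs[, pcs, drop = FALSE],
                   by = cs[, c(key_cols, "subregion"), drop = FALSE],
                   FUN = mean)
  agg[order(agg$fragment_id, agg$subregion), , drop = FALSE]
}

#' Which components are dominated by the LRTC features
#'
#' Sums the per-component contribution (%) of the scaling-exponent
#' features (SEV1, SEV2); useful for identifying fluctuation-driven
#' components in recovery studies.
#'
#' @param pca An `eeg_pca`.
#' @return Named numeric vector, one entry per PC.
#' @export
lrtc_contribution <- function(pca) {
  sev <- intersect(c("SEV1", "SEV2"), rownames(pca$contributions))
  if (length(sev) == 0) return(setNames(numeric(ncol(pca$contributions)),
                                        colnames(pca$contributions)))
  colSums(pca$contributions[sev, , drop = FALSE])
}

#' Render a topographic scalp map of per-channel values
#'
#' Inverse-distance-weighted interpolation of channel values onto the
#' unit disc (vertex view, nose up, left ear left). A thin plotting
#' utility: returns the interpolated grid and optionally writes a PNG.
#'
#' @param values Named numeric vector (names are channel labels).
#' @param file Optional PNG path.
#' @param grid_n Grid resolution per axis.
#' @return Invisibly, the `grid_n x grid_n` matrix of interpolated
#'   values (NA outside the disc).
#' @export
topomap <- function(values, file = NULL, grid_n = 67) {
  if (length(values) < 32) stop("need at least 32 mapped channels")
  pos <- electrode_positions(names(values))
  gx <- seq(-1, 1, length.out = grid_n)
  grid <- matrix(NA_real_, grid_n, grid_n)
  for (i in seq_len(grid_n)) {
    for (j in seq_len(grid_n)) {
      if (gx[i]^2 + gx[j]^2 > 1) next
      d2 <- (pos$x - gx[i])^2 + (pos$y - gx[j])^2
      if (min(d2) < 1e-12) {
        grid[j, i] <- values[which.min(d2)]
      } else {
        w <- 1 / d2^1.5
        grid[j, i] <- sum(w * values) / sum(w)
      }
    }
  }
  if (!is.null(file)) {
    grDevices::png(file, width = 480, height = 480)
    graphics::image(gx, gx, t(grid), asp = 1, axes = FALSE, xlab = "", ylab = "",
                    col = grDevices::hcl.colors(64, "RdBu", rev = TRUE))
    graphics::points(pos$x, pos$y, pch = 20, cex = 0.5)
    grDevices::dev.off()
  }
  invisible(grid)
}
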