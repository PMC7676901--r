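#' Standard 64-channel 10-20 scalp labels
#'
#' Returns the conventional 64 scalp electrode labels of an extended
#' 10-20 layout (BioSemi 64-channel ordering, A1-A32 then B1-B32).
#'
#' @param n Number of labels to return. With `n < 64` a reduced montage is
#'   returned that still covers all six scalp subregions (frontal, central,
#'   left/right temporal, parietal, occipital), so that subregion averaging
#'   remains well defined on small simulated cohorts.
#' @return Character vector of channel labels.
#' @export
scalp_labels <- function(n = 64) {
  full <- c(
    "Fp1", "AF7", "AF3", "F1", "F3", "F5", "F7", "FT7", "FC5", "FC3",
    "FC1", "C1", "C3", "C5", "T7", "TP7", "CP5", "CP3", "CP1", "P1",
    "P3", "P5", "P7", "P9", "PO7", "PO3", "O1", "Iz", "Oz", "POz",
    "Pz", "CPz", "Fpz", "Fp2", "AF8", "AF4", "AFz", "Fz", "F2", "F4",
    "F6", "F8", "FT8", "FC6", "FC4", "FC2", "FCz", "Cz", "C2", "C4",
    "C6", "T8", "TP8", "CP6", "CP4", "CP2", "P2", "P4", "P6", "P8",
    "P10", "PO8", "PO4", "O2"
  )
  if (n >= 64) return(full[seq_len(min(n, 64))])
  # reduced montages keep 6-subregion coverage: cycle through subregions
  reduced <- c(
    "Fz", "Cz", "T7", "T8", "Pz", "Oz",          # one per subregion
    "F3", "C3", "TP7", "TP8", "P3", "O1",
    "F4", "C4", "FT7", "FT8", "P4", "O2",
    "Fp1", "FC1", "Fp2", "FC2", "CP1", "POz"
  )
  if (n <= length(reduced)) return(reduced[seq_len(n)])
  c(reduced, setdiff(full, reduced))[seq_len(n)]
}

#' Map channel labels to the six scalp subregions
#'
#' Channels are grouped into frontal, central, left/right temporal,
#' parietal, and occipital subregions. The assignment follows the usual
#' 10-20 prefix convention: `Fp*`, `AF*`, `F*` are frontal; `FC*`, `C*`
#' central; `FT*`, `T*`, `TP*` temporal (split by hemisphere on the
#' trailing digit, odd = left, even = right); `CP*`, `P*` parietal;
#' `PO*`, `O*`, `Iz` occipital. The table is a package default and can be
#' overridden by supplying any named vector where `subregion_map()` is
#' accepted.
#'
#' @param labels Character vector of channel labels.
#' @return Named character vector mapping each label to one of
#'   `"frontal"`, `"central"`, `"left_temporal"`, `"right_temporal"`,
#'   `"parietal"`, `"occipital"`.
#' @export
subregion_map <- function(labels = scalp_labels()) {
  classify <- function(lab) {
    u <- toupper(lab)
    if (grepl("^(FP|AF|F)[0-9Z]*$", u) && !grepl("^(FC|FT)", u)) return("frontal")
    if (grepl("^(FC|C)[0-9Z]*$", u) && !grepl("^CP", u)) return("central")
    if (grepl("^(FT|TP|T)[0-9]+$", u)) {
      d <- as.integer(sub("^[A-Z]+", "", u))
      return(if (d %% 2 == 1) "left_temporal" else "right_temporal")
    }
    if (grepl("^(CP|P)[0-9Z]*$", u) && !grepl("^PO", u)) return("parietal")
    if (grepl("^(PO|O)[0-9Z]*$", u) || u == "IZ") return("occipital")
    NA_character_
  }
  out <- vapply(labels, classify, character(1))
  if (anyNA(out)) {
    stop("unmapped channel label(s): ", paste(labels[is.na(out)], collapse = ", "))
  }
  out
}

#' Approximate 2-D electrode positions for topographic maps
#'
#' Projects 10-20 labels onto the unit disc (vertex view, nose up, left
#' ear left) from a coarse built-in table of angular positions. Intended
#' only for rendering component-score topographies, not for source work.
#'
#' @param labels Channel labels.
#' @return Data frame with columns `label`, `x`, `y`.
#' @export
electrode_positions <- function(labels = scalp_labels()) {
  ring <- function(lab) {
    u <- toupper(lab)
    if (grepl("^FP", u)) return(c(row = -4, mid = grepl("Z$", u)))
    if (grepl("^AF", u)) return(c(row = -3, 0))
    if (grepl("^F[0-9Z]", u)) return(c(row = -2, 0))
    if (grepl("^(FC|FT)", u)) return(c(row = -1, 0))
    if (grepl("^(C[0-9Z]|T[0-9])", u)) return(c(row = 0, 0))
    if (grepl("^(CP|TP)", u)) return(c(row = 1, 0))
    if (grepl("^P[0-9Z]", u)) return(c(row = 2, 0))
    if (grepl("^PO", u)) return(c(row = 3, 0))
    c(row = 4, 0) # O*, Iz
  }
  lat <- function(lab) {
    u <- toupper(lab)
    if (grepl("Z$", u)) return(0)
    d <- suppressWarnings(as.integer(sub("^[A-Z]+", "", u)))
    if (is.na(d)) return(0)
    side <- if (d %% 2 == 1) -1 else 1
    side * ceiling(d / 2)
  }
  rows <- vapply(labels, function(l) ring(l)[1], numeric(1))
  lats <- vapply(labels, lat, numeric(1))
  # temporal chains (T7/T8 etc.) sit on the outer rim
  outer <- grepl("^(FT|TP|T)[0-9]+$", toupper(labels)) |
    abs(lats) >= 4 | toupper(labels) %in% c("P9", "P10")
  r <- pmin(0.25 * abs(lats) + 0.12 * abs(rows), 1)
  r[outer] <- 1
  r[lats == 0] <- 0.22 * abs(rows[lats == 0])
  ang <- atan2(sign(lats) * pmax(abs(lats), 0.01 * (lats != 0)), -rows)
  data.frame(
    label = labels,
    x = r * sin(ang),
    y = r * cos(ang) * -1 * -1, # nose (front, negative row) up
    stringsAsFactors = FALSE
  )
}
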