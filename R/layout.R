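## BioSemi 64-channel label set, international 10-20 (extended) names.
BIOSEMI64 <- c(
  "Fp1", "AF7", "AF3", "F1", "F3", "F5", "F7", "FT7", "FC5", "FC3", "FC1",
  "C1", "C3", "C5", "T7", "TP7", "CP5", "CP3", "CP1", "P1", "P3", "P5",
  "P7", "P9", "PO7", "PO3", "O1", "Iz", "Oz", "POz", "Pz", "CPz", "Fpz",
  "Fp2", "AF8", "AF4", "AFz", "Fz", "F2", "F4", "F6", "F8", "FT8", "FC6",
  "FC4", "FC2", "FCz", "Cz", "C2", "C4", "C6", "T8", "TP8", "CP6", "CP4",
  "CP2", "P2", "P4", "P6", "P8", "P10", "PO8", "PO4", "O2")

## sagittal rows in 10% (18 degree) steps anterior of Cz
ROW_STEPS <- c(Fp = 4, AF = 3, F = 2, FT = 1, FC = 1, C = 0, T = 0,
               TP = -1, CP = -1, P = -2, PO = -3, O = -4, I = -5)

parse_1020_label <- function(label) {
  m <- regmatches(label, regexec("^([A-Za-z]+?)(z|[0-9]+)$", label))[[1]]
  if (length(m) != 3L) stopf("unparseable 10-20 label: %s", label)
  row <- m[2]
  if (!row %in% names(ROW_STEPS)) stopf("unknown 10-20 row in label %s", label)
  if (m[3] == "z") {
    lat <- 0
  } else {
    num <- as.integer(m[3])
    lat <- ceiling(num / 2) * if (num %% 2 == 1) -1 else 1  # odd = left
  }
  c(sagittal = unname(ROW_STEPS[row]), lateral = lat)
}

#' Idealized spherical 10-20 electrode layout (64 channels)
#'
#' Unit-sphere positions for the standard BioSemi 64-channel label set,
#' built geometrically from the 10-20 arc construction: each 10% step along
#' an arc is 18 degrees, positions are laid out by azimuthal-equidistant
#' projection around the vertex. Axes: x = right, y = up (Cz at the vertex),
#' z = anterior. The layout is an idealized spherical head, adequate for
#' spatial component weighting and spline interpolation; it is not a
#' digitized montage.
#'
#' @param labels channel names to lay out (default: the BioSemi 64 set).
#' @return data.frame with columns `label`, `x`, `y`, `z`; unit-norm rows.
#' @export
electrode_layout <- function(labels = BIOSEMI64) {
  pos <- t(vapply(labels, function(lb) {
    st <- parse_1020_label(lb)
    r <- sqrt(sum(st^2))
    theta <- r * 18 * pi / 180
    if (r < 1e-12) return(c(0, 1, 0))
    dz <- st[["sagittal"]] / r   # anterior component of horizontal direction
    dx <- st[["lateral"]] / r    # rightward component
    c(sin(theta) * dx, cos(theta), sin(theta) * dz)
  }, numeric(3)))
  data.frame(label = labels, x = pos[, 1], y = pos[, 2], z = pos[, 3],
             row.names = NULL)
}

layout_matrix <- function(layout) {
  m <- as.matrix(layout[, c("x", "y", "z")])
  rownames(m) <- layout$label
  m
}

## angular distance (radians) from every layout electrode to a center label
angular_dist <- function(layout, center) {
  m <- layout_matrix(layout)
  if (!center %in% rownames(m)) stopf("electrode %s not in layout", center)
  cosang <- pmin(1, pmax(-1, m %*% m[center, ]))
  acos(as.numeric(cosang))
}
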