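#' Sensor montages
#'
#' An EEG montage is a set of channel labels with unit-sphere 3-D positions
#' (x = right, y = anterior, z = superior). Positions are used for spherical
#' spline interpolation of bad channels and for building the sensor adjacency
#' used by cluster-level tests.
#'
#' @name montage
NULL

# spherical linear interpolation between two unit vectors
slerp <- function(p, q, t) {
  omega <- acos(max(-1, min(1, sum(p * q))))
  if (omega < 1e-12) return(p)
  (sin((1 - t) * omega) * p + sin(t * omega) * q) / sin(omega)
}

# unit vector from inclination (deg from vertex) and azimuth
# (deg from anterior midline, positive toward the right ear)
sph_pos <- function(incl, az) {
  ir <- incl * pi / 180
  ar <- az * pi / 180
  c(x = sin(ir) * sin(ar), y = sin(ir) * cos(ar), z = cos(ir))
}

#' Default 32-channel extended 10-20 montage
#'
#' Idealized spherical montage: the classic 10-20 outer ring (Fp1/Fp2 ... O1/O2)
#' lies at 72 degrees of inclination from the vertex, midline electrodes step in
#' 18-degree (10%) increments, and intermediate 10-10 electrodes (F3, FC3, CP4,
#' PO3, ...) are placed by great-circle interpolation between the midline and
#' outer-ring electrodes of their row. The montage includes FCz, the reference
#' used for connectivity analyses.
#'
#' @return A data frame with columns `label`, `x`, `y`, `z`; 32 rows, all
#'   positions of unit norm.
#' @examples
#' m <- standard_montage_32()
#' stopifnot(nrow(m) == 32, "FCz" %in% m$label)
#' @export
standard_montage_32 <- function() {
  # midline inclinations per row letter; azimuth 0 (front) or 180 (back)
  mid <- list(
    Fz = c(36, 0), FCz = c(18, 0), Cz = c(0, 0), CPz = c(18, 180),
    Pz = c(36, 180), POz = c(54, 180)
  )
  # outer ring: inclination 72, azimuth from the front midline
  ring <- list(
    Fp1 = -18, Fp2 = 18, F7 = -54, F8 = 54, FT7 = -72, FT8 = 72,
    T7 = -90, T8 = 90, TP7 = -108, TP8 = 108, P7 = -126, P8 = 126,
    O1 = -162, O2 = 162
  )
  pos <- list()
  for (lab in names(mid)) pos[[lab]] <- sph_pos(mid[[lab]][1], mid[[lab]][2])
  for (lab in names(ring)) pos[[lab]] <- sph_pos(72, ring[[lab]])
  # intermediate electrodes: halfway along the great circle between the
  # midline electrode of the row and the corresponding outer-ring electrode
  inter <- list(
    F3 = c("Fz", "F7"), F4 = c("Fz", "F8"),
    FC3 = c("FCz", "FT7"), FC4 = c("FCz", "FT8"),
    C3 = c("Cz", "T7"), C4 = c("Cz", "T8"),
    CP3 = c("CPz", "TP7"), CP4 = c("CPz", "TP8"),
    P3 = c("Pz", "P7"), P4 = c("Pz", "P8")
  )
  for (lab in names(inter)) {
    pr <- inter[[lab]]
    pos[[lab]] <- slerp(pos[[pr[1]]], pos[[pr[2]]], 0.5)
  }
  # PO3/PO4 interpolate toward the (virtual) PO7/PO8 ring positions
  pos[["PO3"]] <- slerp(pos[["POz"]], sph_pos(72, -144), 0.5)
  pos[["PO4"]] <- slerp(pos[["POz"]], sph_pos(72, 144), 0.5)

  order32 <- c(
    "Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8",
    "FT7", "FC3", "FCz", "FC4", "FT8",
    "T7", "C3", "Cz", "C4", "T8",
    "TP7", "CP3", "CPz", "CP4", "TP8",
    "P7", "P3", "Pz", "P4", "P8",
    "PO3", "POz", "PO4", "O1", "O2"
  )
  m <- do.call(rbind, pos[order32])
  out <- data.frame(label = order32, x = m[, 1], y = m[, 2], z = m[, 3],
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("montage", "data.frame")
  out
}

#' Subset a montage by channel labels
#'
#' @param montage a montage data frame
#' @param labels channel labels to keep, in the requested order
#' @return the subset montage
#' @export
montage_subset <- function(montage, labels) {
  idx <- match(labels, montage$label)
  if (anyNA(idx)) {
    stop("labels not in montage: ", paste(labels[is.na(idx)], collapse = ", "))
  }
  out <- montage[idx, , drop = FALSE]
  rownames(out) <- NULL
  out
}

validate_montage <- function(montage) {
  stopifnot(is.data.frame(montage),
            all(c("label", "x", "y", "z") %in% names(montage)))
  if (anyDuplicated(montage$label)) stop("duplicated channel labels in montage")
  nrm <- sqrt(montage$x^2 + montage$y^2 + montage$z^2)
  if (any(abs(nrm - 1) > 1e-6)) stop("montage positions must have unit norm")
  invisible(montage)
}
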