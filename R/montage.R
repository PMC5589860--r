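#' Electrode montages
#'
#' A montage holds unique channel labels and 3-D head-centered positions
#' (millimeters). All downstream geometry (spline interpolation, lead
#' fields) assumes the positions lie on a sphere of common radius; use
#' [fit_to_sphere()] to enforce that.
#'
#' @param labels character vector of unique channel names
#' @param positions numeric matrix, one row per channel, columns x/y/z in mm
#'   (x right, y anterior, z superior)
#' @return an object of class `montage`
#' @export
montage <- function(labels, positions) {
  labels <- as.character(labels)
  positions <- as.matrix(positions)
  if (anyDuplicated(labels)) stop("duplicate channel labels in montage")
  if (nrow(positions) != length(labels) || ncol(positions) != 3L)
    stop("positions must be a length(labels) x 3 matrix")
  storage.mode(positions) <- "double"
  rownames(positions) <- labels
  structure(list(labels = labels, positions = positions), class = "montage")
}

#' @export
print.montage <- function(x, ...) {
  r <- sqrt(rowSums(x$positions^2))
  cat(sprintf("<montage> %d channels, radius %.1f-%.1f mm\n",
              length(x$labels), min(r), max(r)))
  invisible(x)
}

# Sagittal/lateral angle table for the synthetic 64-channel 10-10-style cap.
# alpha: rotation from the vertex toward nasion (+) / inion (-), degrees.
# beta:  lateral rotation, positive to the right, degrees.
.montage64_angles <- function() {
  mid <- data.frame(
    label = c("Fpz", "AFz", "Fz", "FCz", "Cz", "CPz", "Pz", "POz", "Oz", "Iz"),
    alpha = c(90, 72, 54, 36, 0, -36, -54, -72, -90, -108),
    beta  = 0)
  lat <- function(left, right, alpha, betas) {
    data.frame(label = c(left, right), alpha = alpha, beta = c(-betas, betas))
  }
  rbind(
    mid,
    lat("Fp1", "Fp2", 90, 18),
    lat(c("AF7", "AF3"), c("AF8", "AF4"), 72, c(50, 20)),
    lat(c("F7", "F5", "F3", "F1"), c("F8", "F6", "F4", "F2"),
        54, c(56, 42, 28, 14)),
    lat(c("FT7", "FC5", "FC3", "FC1"), c("FT8", "FC6", "FC4", "FC2"),
        27, c(70, 42, 28, 14)),
    lat(c("T7", "C5", "C3", "C1"), c("T8", "C6", "C4", "C2"),
        0, c(90, 42, 28, 14)),
    lat(c("TP7", "CP5", "CP3", "CP1"), c("TP8", "CP6", "CP4", "CP2"),
        -27, c(70, 42, 28, 14)),
    lat(c("P9", "P7", "P5", "P3", "P1"), c("P10", "P8", "P6", "P4", "P2"),
        -54, c(78, 56, 42, 28, 14)),
    lat(c("PO7", "PO3"), c("PO8", "PO4"), -72, c(50, 20)),
    lat("O1", "O2", -90, 18))
}

#' Synthetic 64-channel 10-10-style montage
#'
#' Builds the packaged 64-electrode cap. Positions are a deterministic
#' geometric construction (not measured Biosemi coordinates): each electrode
#' direction is obtained from a sagittal angle `alpha` (vertex toward
#' nasion/inion) and a lateral angle `beta`, then scaled to the head radius.
#' The label set matches the common 64-channel 10-10 naming so that outputs
#' read naturally; the coordinates themselves are synthetic stand-ins.
#'
#' @param head_radius scalp sphere radius in mm
#' @return a [montage()]
#' @export
make_montage_64 <- function(head_radius = 85) {
  ang <- .montage64_angles()
  a <- ang$alpha * pi / 180
  b <- ang$beta * pi / 180
  pos <- cbind(x = sin(b),
               y = cos(b) * sin(a),
               z = cos(b) * cos(a)) * head_radius
  montage(ang$label, pos)
}

#' Read / write `.sfp` electrode position files
#'
#' Plain-text format with one `label x y z` line per electrode,
#' whitespace-separated, coordinates in mm.
#'
#' @param path file path
#' @return [read_sfp()] returns a [montage()]; [write_sfp()] returns `path`
#'   invisibly.
#' @export
read_sfp <- function(path) {
  tab <- utils::read.table(path, header = FALSE, col.names = c("label", "x", "y", "z"),
                           colClasses = c("character", rep("numeric", 3)))
  montage(tab$label, as.matrix(tab[, c("x", "y", "z")]))
}

#' @param m a [montage()]
#' @rdname read_sfp
#' @export
write_sfp <- function(m, path) {
  stopifnot(inherits(m, "montage"))
  tab <- data.frame(label = m$labels, m$positions)
  utils::write.table(tab, path, quote = FALSE, row.names = FALSE,
                     col.names = FALSE, sep = "\t")
  invisible(path)
}

#' Project electrode positions radially onto a sphere
#'
#' Radial projection preserves each electrode's angular coordinates and sets
#' its distance from the head center to `head_radius`.
#'
#' @param m a [montage()]
#' @param head_radius target sphere radius in mm
#' @return a [montage()] with all positions at `|r| = head_radius`
#' @export
fit_to_sphere <- function(m, head_radius = 85) {
  stopifnot(inherits(m, "montage"))
  r <- sqrt(rowSums(m$positions^2))
  if (any(r == 0)) stop("electrode at head center cannot be projected")
  montage(m$labels, m$positions * (head_radius / r))
}

#' Load a montage file (alias for the `.sfp` reader)
#' @inheritParams read_sfp
#' @export
load_montage <- function(path) read_sfp(path)
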