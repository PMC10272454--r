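# Idealised 129-channel geodesic sensor layout.
#
# Real geodesic nets place ~129 electrodes near-uniformly over a spherical
# cap extending a little below the equator, with the vertex electrode (Cz)
# used as the recording reference. The packaged layout is an idealisation:
# 128 scalp channels on a Fibonacci spiral over the cap plus Cz at the
# vertex. It is deterministic and makes no claim of anatomical fidelity.

#' Idealised 129-channel geodesic layout
#'
#' @return data.frame with columns `label` (`E1`..`E128`, `Cz`) and unit
#'   3D positions `x`, `y`, `z` (y toward the nose, z up).
#' @export
layout_geodesic_129 <- function() {
  n <- 128L
  z_lo <- -0.25; z_hi <- 0.985
  i <- seq_len(n)
  z <- z_hi - (i - 0.5) / n * (z_hi - z_lo)
  golden <- pi * (3 - sqrt(5))
  th <- golden * i
  r <- sqrt(pmax(0, 1 - z^2))
  d <- data.frame(label = c(sprintf("E%d", i), "Cz"),
                  x = c(r * cos(th), 0),
                  y = c(r * sin(th), 0),
                  z = c(z, 1),
                  stringsAsFactors = FALSE)
  rownames(d) <- d$label
  d
}

#' Canonical scalp sites of the idealised layout
#'
#' Unit vectors for the left/right sensorimotor hand areas and the central
#' midline, used to place rhythm topographies in the simulator.
#' @return named list of unit 3-vectors.
#' @export
sensorimotor_sites <- function() {
  unit <- function(v) v / sqrt(sum(v^2))
  list(left = unit(c(-0.65, 0.10, 0.75)),
       right = unit(c(0.65, 0.10, 0.75)),
       central = unit(c(0, 0.05, 1)))
}

#' Electrodes of the layout nearest to a scalp site
#'
#' @param layout a layout data.frame (see [layout_geodesic_129()]).
#' @param site unit 3-vector.
#' @param k number of electrodes.
#' @param exclude labels never returned (default the reference `Cz`).
#' @return character vector of `k` labels, nearest first.
#' @export
nearest_electrodes <- function(layout, site, k = 3L, exclude = "Cz") {
  keep <- !(layout$label %in% exclude)
  pos <- as.matrix(layout[keep, c("x", "y", "z")])
  ang <- acos(pmin(1, pmax(-1, pos %*% site)))
  layout$label[keep][order(ang)][seq_len(k)]
}

#' Read / write a sensor-layout file
#'
#' Tab-delimited text: `label`, `x`, `y`, `z` (unit sphere).
#' @param path file path.
#' @return [read_layout()]: the layout data.frame.
#' @export
read_layout <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("label", "x", "y", "z") %in% names(d)))
  rownames(d) <- d$label
  d
}

#' @rdname read_layout
#' @param layout layout data.frame to write.
#' @export
write_layout <- function(layout, path) {
  utils::write.table(layout, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
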