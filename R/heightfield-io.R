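# Height-field export/import.
#
# Formats: delimited text (lossless round trip), 16-bit grayscale TIFF
# heightmap with a JSON sidecar carrying the grid geometry and height scale,
# 8-bit PNG preview, and ASCII STL surface mesh.

#' Export a height field
#'
#' @param field a [height_field()].
#' @param path output file path.
#' @param format one of `"txt"` (tab-delimited grid with a commented
#'   geometry header), `"tif16"` (16-bit grayscale TIFF + `<path>.json`
#'   sidecar with spacing, origin and height range), `"png"` (8-bit
#'   grayscale preview + sidecar), `"stl"` (ASCII STL triangle mesh,
#'   `2*(nx-1)*(ny-1)` facets).
#' @return `path`, invisibly.
#' @export
export_heightfield <- function(field, path,
                               format = c("txt", "tif16", "png", "stl")) {
  format <- match.arg(format)
  dir <- dirname(path)
  if (!dir.exists(dir) || file.access(dir, 2) != 0)
    stop_tex(sprintf("cannot write to '%s'", dir), "io_error")
  switch(format,
    txt = write_hf_txt(field, path),
    tif16 = write_hf_raster(field, path, bits = 16L),
    png = write_hf_raster(field, path, bits = 8L),
    stl = write_hf_stl(field, path))
  invisible(path)
}

#' Read a height field written by [export_heightfield()]
#'
#' @param path file path (`txt`, `tif16` or `png`; raster formats require
#'   the JSON sidecar written at export time).
#' @param format format the file was written in.
#' @return a [height_field()].
#' @export
read_heightfield <- function(path, format = c("txt", "tif16", "png")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_tex(sprintf("no such file '%s'", path), "io_error")
  if (format == "txt") return(read_hf_txt(path))
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  img <- if (format == "tif16") tiff::readTIFF(path) else png::readPNG(path)
  h <- t(img)[, rev(seq_len(nrow(img))), drop = FALSE]  # undo raster orientation
  heights <- h * (side$height_max - side$height_min) + side$height_min
  height_field(heights, side$spacing, unlist(side$origin))
}

write_hf_txt <- function(field, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# spacing_mm %.17g", field$spacing),
    sprintf("# origin_mm %.17g %.17g", field$origin[1], field$origin[2])), con)
  utils::write.table(format(field$heights, digits = 17, trim = TRUE,
                            scientific = TRUE),
                     con, sep = "\t", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
}

read_hf_txt <- function(path) {
  hdr <- readLines(path, n = 2L)
  spacing <- as.numeric(strsplit(hdr[1], " ")[[1]][3])
  origin <- as.numeric(strsplit(hdr[2], " ")[[1]][3:4])
  m <- as.matrix(utils::read.table(path, skip = 2L, sep = "\t"))
  dimnames(m) <- NULL
  height_field(m, spacing, origin)
}

# Raster heightmap: rows of the image run along -y so the picture reads with
# x rightward and y upward; heights are min/max normalised to [0, 1].
write_hf_raster <- function(field, path, bits) {
  h <- field$heights
  rng <- range(h)
  span <- if (diff(rng) == 0) 1 else diff(rng)
  img <- t(h[, rev(seq_len(ncol(h))), drop = FALSE])
  img <- (img - rng[1]) / span
  # quantize explicitly so the round-trip error bound is the format's
  levels <- 2^bits - 1
  img <- round(img * levels) / levels
  if (bits == 16L) {
    tiff::writeTIFF(img, path, bits.per.sample = 16L)
  } else {
    png::writePNG(img, path)
  }
  jsonlite::write_json(
    list(spacing = field$spacing, origin = field$origin,
         height_min = rng[1], height_max = rng[1] + span, bits = bits),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
}

write_hf_stl <- function(field, path) {
  h <- field$heights
  nx <- nrow(h); ny <- ncol(h)
  x <- field_x(field); y <- field_y(field)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("solid heightfield", con)
  tri <- function(p1, p2, p3) {
    u <- p2 - p1; v <- p3 - p1
    n <- c(u[2] * v[3] - u[3] * v[2],
           u[3] * v[1] - u[1] * v[3],
           u[1] * v[2] - u[2] * v[1])
    nn <- sqrt(sum(n^2)); if (nn > 0) n <- n / nn
    c(sprintf("facet normal %g %g %g", n[1], n[2], n[3]),
      "  outer loop",
      sprintf("    vertex %g %g %g", c(p1[1], p2[1], p3[1]),
              c(p1[2], p2[2], p3[2]), c(p1[3], p2[3], p3[3])),
      "  endloop", "endfacet")
  }
  out <- vector("list", 2L * (nx - 1L) * (ny - 1L))
  k <- 0L
  for (j in seq_len(ny - 1L)) {
    for (i in seq_len(nx - 1L)) {
      p00 <- c(x[i], y[j], h[i, j]);      p10 <- c(x[i + 1], y[j], h[i + 1, j])
      p01 <- c(x[i], y[j + 1], h[i, j + 1]); p11 <- c(x[i + 1], y[j + 1], h[i + 1, j + 1])
      out[[k <- k + 1L]] <- tri(p00, p10, p11)
      out[[k <- k + 1L]] <- tri(p00, p11, p01)
    }
  }
  writeLines(unlist(out), con)
  writeLines("endsolid heightfield", con)
}

#' Count facets in an ASCII STL file
#' @param path STL path.
#' @return integer facet count.
#' @export
count_stl_facets <- function(path) {
  sum(grepl("^\\s*facet normal", readLines(path)))
}
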