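## Synthetic 3D phantoms: proton-density volumes for the virtual scanner.

#' Proton-density phantom
#'
#' @param density 3D array of non-negative proton density (arbitrary units).
#' @param voxel_size scalar or 3-vector voxel edge, meters.
#' @param T2 optional 3D array of T2 values, seconds (same shape).
#' @return object of class `phantom`.
#' @export
phantom <- function(density, voxel_size, T2 = NULL) {
  stopifnot(length(dim(density)) == 3L, all(is.finite(density)),
            all(density >= 0))
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  stopifnot(length(voxel_size) == 3L, all(voxel_size > 0))
  if (!is.null(T2)) stopifnot(all(dim(T2) == dim(density)), all(T2 > 0))
  structure(list(density = density, voxel_size = as.numeric(voxel_size),
                 T2 = T2), class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  d <- dim(x$density)
  cat(sprintf("<phantom> %d x %d x %d voxels of %.2f x %.2f x %.2f mm\n",
              d[1], d[2], d[3], x$voxel_size[1] * 1e3, x$voxel_size[2] * 1e3,
              x$voxel_size[3] * 1e3))
  invisible(x)
}

# voxel center coordinates along one axis, centered on 0
.axis_coords <- function(n, vox) (seq_len(n) - (n + 1) / 2) * vox

# 5x7 raster font: one string of 35 chars per glyph, rows top to bottom
.font5x7 <- list(
  "A" = "01110100011000111111100011000110001",
  "B" = "11110100011000111110100011000111110",
  "C" = "01110100011000010000100001000101110",
  "D" = "11100100101000110001100011001011100",
  "E" = "11111100001000011110100001000011111",
  "F" = "11111100001000011110100001000010000",
  "G" = "01110100011000010111100011000101111",
  "H" = "10001100011000111111100011000110001",
  "I" = "01110001000010000100001000010001110",
  "J" = "00111000100001000010000101001001100",
  "K" = "10001100101010011000101001001010001",
  "L" = "10000100001000010000100001000011111",
  "M" = "10001110111010110101100011000110001",
  "N" = "10001110011010110011100011000110001",
  "O" = "01110100011000110001100011000101110",
  "P" = "11110100011000111110100001000010000",
  "Q" = "01110100011000110001101011001001101",
  "R" = "11110100011000111110101001001010001",
  "S" = "01111100001000001110000010000111110",
  "T" = "11111001000010000100001000010000100",
  "U" = "10001100011000110001100011000101110",
  "V" = "10001100011000110001100010101000100",
  "W" = "10001100011000110101101011101110001",
  "X" = "10001100010101000100010101000110001",
  "Y" = "10001100010101000100001000010000100",
  "Z" = "11111000010001000100010001000011111",
  "0" = "01110100011001110101110011000101110",
  "1" = "00100011000010000100001000010001110",
  "2" = "01110100010000100110010001000011111",
  "3" = "11111000100010000110000011000101110",
  "4" = "00010001100101010010111110001000010",
  "5" = "11111100001111000001000011000101110",
  "6" = "00110010001000011110100011000101110",
  "7" = "11111000010001000100010001000010000",
  "8" = "01110100011000101110100011000101110",
  "9" = "01110100011000101111000010001001100",
  " " = "00000000000000000000000000000000000",
  "!" = "00100001000010000100001000000000100",
  "?" = "01110100010000100110001000000000100")

# rasterize a message into a logical matrix (rows x cols), TRUE = ink
.raster_message <- function(message) {
  chars <- strsplit(toupper(message), "")[[1]]
  unknown <- setdiff(chars, names(.font5x7))
  if (length(unknown))
    stop("no glyph for character(s): ", paste(unique(unknown), collapse = " "))
  ncols <- length(chars) * 6L - 1L
  M <- matrix(FALSE, 7L, ncols)
  for (i in seq_along(chars)) {
    bits <- as.integer(strsplit(.font5x7[[chars[i]]], "")[[1]]) == 1L
    M[, (i - 1L) * 6L + 1:5] <- matrix(bits, 7L, 5L, byrow = TRUE)
  }
  M
}

#' Spherical mystery phantom with an embedded message
#'
#' A uniform sphere of doped water (density 1) with a message carved as
#' signal-void glyphs on the transverse mid-plane (a slab of zero density in
#' the shape of the rasterized text), mimicking a sealed phantom whose
#' content is only revealed by imaging it.
#'
#' @param diameter sphere diameter, meters (default 10 cm).
#' @param message text to embed (A-Z, 0-9, space, `!`, `?`); empty string
#'   gives a plain uniform sphere.
#' @param n voxels per axis of the cubic phantom grid.
#' @param margin grid extent as a multiple of the diameter.
#' @param glyph_depth axial thickness of the signal-void message plate,
#'   meters; thick enough that coarse slice grids intersect it.
#' @return a [phantom()].
#' @export
make_mystery_phantom <- function(diameter = 0.10, message = "HI", n = 96L,
                                 margin = 1.1, glyph_depth = 0.012) {
  stopifnot(diameter > 0, n >= 16L)
  extent <- diameter * margin
  vox <- extent / n
  co <- .axis_coords(n, vox)
  r2 <- outer(outer(co^2, co^2, `+`), co^2, `+`)
  dens <- array(as.numeric(r2 <= (diameter / 2)^2), c(n, n, n))
  if (nzchar(message)) {
    glyphs <- .raster_message(message)
    # fit the text into 70% of the diameter, glyph pixels square
    px <- 0.7 * diameter / ncol(glyphs)
    if (px < vox)
      stop("message too long for this diameter/resolution: glyph pixels (",
           signif(px * 1e3, 3), " mm) smaller than voxels (",
           signif(vox * 1e3, 3), " mm)")
    half_th <- max(glyph_depth, 1.5 * vox) / 2   # slab half-thickness
    iz <- which(abs(co) <= half_th)
    # map x (readout) to text columns, y to rows (top row at +y)
    jcol <- floor((co + 0.5 * ncol(glyphs) * px) / px) + 1L
    irow <- floor((0.5 * nrow(glyphs) * px - co) / px) + 1L
    for (ix in seq_len(n)) {
      cj <- jcol[ix]
      if (cj < 1L || cj > ncol(glyphs)) next
      for (iy in seq_len(n)) {
        ri <- irow[iy]
        if (ri < 1L || ri > nrow(glyphs)) next
        if (glyphs[ri, cj]) dens[ix, iy, iz] <- 0
      }
    }
  }
  phantom(dens, vox)
}

#' Two-syringe phantom
#'
#' Two parallel water-filled cylinders along the bore axis, the classic
#' first-image test object.
#'
#' @param n voxels per axis.
#' @param fov grid extent, meters.
#' @param radius cylinder radius, meters.
#' @param length cylinder length, meters.
#' @param separation center-to-center distance of the two cylinders, meters
#'   (must exceed `2*radius` for disjoint cylinders).
#' @return a [phantom()].
#' @export
make_syringe_phantom <- function(n = 64L, fov = 0.11, radius = 0.011,
                                 length = 0.08, separation = 0.045) {
  stopifnot(separation > 2 * radius, 2 * radius < fov, length <= fov)
  vox <- fov / n
  co <- .axis_coords(n, vox)
  dens <- array(0, c(n, n, n))
  inz <- abs(co) <= length / 2
  for (s in c(-1, 1)) {
    d2 <- outer((co - s * separation / 2)^2, co^2, `+`)
    disk <- d2 <= radius^2
    dens[, , inz] <- dens[, , inz] + as.numeric(disk)
  }
  if (any(dens > 1)) stop("cylinders overlap")  # unreachable by precondition
  phantom(dens, vox)
}
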