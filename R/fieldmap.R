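## Field-map data model, mapping-robot emulation, CSV I/O, homogeneity
## metrics, and first-order spherical-harmonic fitting.

#' Gridded field map
#'
#' Samples of the static field vector on a regular grid, the unit all
#' homogeneity metrics, shimming and the virtual scanner consume.  Grid point
#' `(i, j, k)` (0-based) sits at `origin + c(i, j, k) * spacing`
#' (cell-centered convention); samples are stored in raster order with x
#' fastest, then y, then z — the order in which the three-stage mapping robot
#' visits the points.
#'
#' @param origin 3-vector, position of grid point (0,0,0), meters.
#' @param spacing 3-vector (or scalar) of grid steps, meters, all > 0.
#' @param dim integer 3-vector of grid shape.
#' @param B `prod(dim) x 3` matrix of field samples (tesla) in raster order.
#' @param metadata named list; `source`, `created`, `b0_axis` (default "x"),
#'   optionally `current_A` (drive current for gradient-efficiency fits) and
#'   `warnings`.
#' @return object of class `field_map`.
#' @export
field_map <- function(origin, spacing, dim, B, metadata = list()) {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  dim <- as.integer(dim)
  stopifnot(length(origin) == 3L, length(spacing) == 3L, length(dim) == 3L,
            all(spacing > 0), all(dim >= 1L))
  B <- as.matrix(B)
  if (nrow(B) != prod(dim) || ncol(B) != 3L)
    stop("B must be a prod(dim) x 3 matrix")
  if (!all(is.finite(B))) stop("field samples must be finite")
  md <- modifyList(list(source = "unknown", created = NA_character_,
                        b0_axis = "x"), metadata)
  structure(list(origin = as.numeric(origin), spacing = as.numeric(spacing),
                 dim = dim, B = B, metadata = md),
            class = "field_map")
}

#' @export
print.field_map <- function(x, ...) {
  cat(sprintf("<field map> %d x %d x %d grid, spacing (%.1f, %.1f, %.1f) mm\n",
              x$dim[1], x$dim[2], x$dim[3],
              x$spacing[1] * 1e3, x$spacing[2] * 1e3, x$spacing[3] * 1e3))
  mag <- sqrt(rowSums(x$B^2))
  cat(sprintf("  |B|: mean %.3f mT, range [%.3f, %.3f] mT\n",
              mean(mag) * 1e3, min(mag) * 1e3, max(mag) * 1e3))
  invisible(x)
}

#' Grid specification helper
#'
#' Cubic grid of `n^3` points with extent `extent` centered on `center`.
#'
#' @param extent edge length of the sampled cube, meters.
#' @param n points per axis (>= 2).
#' @param center 3-vector, meters.
#' @return list with `origin`, `spacing`, `dim` as used by [simulate_mapping()].
#' @export
grid_spec <- function(extent, n = 11L, center = c(0, 0, 0)) {
  n <- as.integer(n)
  stopifnot(n >= 2L, extent > 0)
  sp <- extent / (n - 1L)
  list(origin = center - extent / 2, spacing = rep(sp, 3L), dim = rep(n, 3L))
}

#' Grid point coordinates of a field map (raster order)
#'
#' @param map a `field_map` or a grid specification list.
#' @return `prod(dim) x 3` matrix of coordinates, x fastest.
#' @export
grid_points <- function(map) {
  idx <- as.matrix(expand.grid(i = seq_len(map$dim[1]) - 1L,
                               j = seq_len(map$dim[2]) - 1L,
                               k = seq_len(map$dim[3]) - 1L))
  sweep(idx * rep(map$spacing, each = nrow(idx)), 2, map$origin, `+`)
}

#' Mapping-robot raster path
#'
#' Order in which the three-axis robot visits the grid: x fastest, then y,
#' then z.  Every grid point is visited exactly once.
#'
#' @param map a `field_map` or grid specification.
#' @return integer matrix `prod(dim) x 3` of 0-based grid indices in visit
#'   order.
#' @export
robot_path <- function(map) {
  as.matrix(expand.grid(i = seq_len(map$dim[1]) - 1L,
                        j = seq_len(map$dim[2]) - 1L,
                        k = seq_len(map$dim[3]) - 1L))
}

#' Simulate a field-mapping run
#'
#' Evaluates the superposed field of `sources` at every grid point in robot
#' raster order and adds i.i.d. Gaussian probe noise per field component.
#' If the grid reaches inside a magnet volume a warning is recorded in the
#' map metadata (the closed-form field is still valid there, but a real probe
#' could not go there).
#'
#' @param sources list of field sources ([cuboid_magnet()] / [loop_coil()]),
#'   or a `halbach_design`.
#' @param grid list with `origin`, `spacing`, `dim` (see [grid_spec()]).
#' @param noise_sd probe noise standard deviation, tesla (>= 0).
#' @param seed integer seed for the noise stream.
#' @param metadata extra metadata entries.
#' @return a [field_map()].
#' @export
simulate_mapping <- function(sources, grid, noise_sd = 0, seed = NULL,
                             metadata = list()) {
  stopifnot(noise_sd >= 0)
  pts <- grid_points(grid)
  if (inherits(sources, "halbach_design")) {
    B <- halbach_field(sources, pts)
    vol_check <- function(p) {
      r <- sqrt(p[, 1]^2 + p[, 2]^2)
      any(r > sources$constraints$min_inner_diameter / 2)
    }
    inside <- vol_check(pts)
  } else {
    B <- superpose(sources, pts)
    inside <- FALSE
    for (s in sources) {
      if (inherits(s, "cuboid_magnet")) {
        q <- abs(sweep(pts, 2, s$center) %*% s$rotation)
        if (any(apply(q, 1, max) < s$edge / 2)) { inside <- TRUE; break }
      }
    }
  }
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    B <- B + matrix(rnorm(length(B), sd = noise_sd), nrow(B), 3)
  }
  md <- modifyList(list(source = "simulated mapping run",
                        created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                        noise_sd_T = noise_sd, seed = seed), metadata)
  if (isTRUE(inside))
    md$warnings <- c(md$warnings, "grid extends inside a magnet volume")
  field_map(grid$origin, grid$spacing, grid$dim, B, md)
}

## CSV dialect: '#'-prefixed JSON metadata line, then
## x_mm,y_mm,z_mm,Bx_mT,By_mT,Bz_mT rows in raster order ---------------------

.fieldmap_cols <- c("x_mm", "y_mm", "z_mm", "Bx_mT", "By_mT", "Bz_mT")

#' Write / read a field map
#'
#' Plain CSV with a leading `#`-prefixed JSON metadata line (shape, spacing
#' and origin in mm, B0 axis, provenance) followed by a
#' `x_mm,y_mm,z_mm,Bx_mT,By_mT,Bz_mT` header and one row per grid point in
#' robot raster order, 12 significant digits.  The round trip is lossless to
#' better than 1e-12 relative.
#'
#' @param map a [field_map()].
#' @param path file path.
#' @return `read_fieldmap` returns a `field_map`; `write_fieldmap` its path,
#'   invisibly.
#' @export
write_fieldmap <- function(map, path) {
  stopifnot(inherits(map, "field_map"))
  md <- map$metadata
  head_json <- jsonlite::toJSON(
    list(shape = map$dim, spacing_mm = map$spacing * 1e3,
         origin_mm = map$origin * 1e3, b0_axis = md$b0_axis,
         source = md$source, created = md$created,
         current_A = md$current_A, noise_sd_T = md$noise_sd_T,
         warnings = md$warnings),
    auto_unbox = TRUE, digits = NA, null = "null")
  pts <- grid_points(map)
  rows <- sprintf("%.12g,%.12g,%.12g,%.12g,%.12g,%.12g",
                  pts[, 1] * 1e3, pts[, 2] * 1e3, pts[, 3] * 1e3,
                  map$B[, 1] * 1e3, map$B[, 2] * 1e3, map$B[, 3] * 1e3)
  writeLines(c(paste0("# ", head_json),
               paste(.fieldmap_cols, collapse = ","), rows), path)
  invisible(path)
}

#' @rdname write_fieldmap
#' @export
read_fieldmap <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  if (length(lines) < 3L) stop("malformed field map: fewer than 3 lines")
  if (!startsWith(lines[1], "# "))
    stop("malformed header at line 1: expected '# {json metadata}'")
  md <- tryCatch(jsonlite::fromJSON(sub("^# ", "", lines[1])),
                 error = function(e) stop("malformed JSON metadata at line 1: ",
                                          conditionMessage(e)))
  hdr <- strsplit(lines[2], ",", fixed = TRUE)[[1]]
  if (!identical(trimws(hdr), .fieldmap_cols))
    stop("malformed header at line 2: expected columns ",
         paste(.fieldmap_cols, collapse = ","))
  n_expect <- prod(md$shape)
  body <- lines[-(1:2)]
  body <- body[nzchar(trimws(body))]
  if (length(body) != n_expect)
    stop(sprintf("row count %d at lines 3-%d does not match declared shape (%s = %d rows)",
                 length(body), length(body) + 2L,
                 paste(md$shape, collapse = "x"), n_expect))
  vals <- strsplit(body, ",", fixed = TRUE)
  bad <- which(lengths(vals) != 6L)
  if (length(bad))
    stop("missing column at line ", bad[1] + 2L)
  num <- matrix(as.numeric(unlist(vals)), ncol = 6L, byrow = TRUE)
  if (anyNA(num)) stop("non-numeric value at line ",
                       which(rowSums(is.na(num)) > 0)[1] + 2L)
  meta <- list(source = md$source, created = md$created, b0_axis = md$b0_axis)
  if (!is.null(md$current_A)) meta$current_A <- md$current_A
  if (!is.null(md$noise_sd_T)) meta$noise_sd_T <- md$noise_sd_T
  if (!is.null(md$warnings)) meta$warnings <- md$warnings
  field_map(md$origin_mm / 1e3, md$spacing_mm / 1e3, md$shape,
            num[, 4:6] / 1e3, meta)
}

#' Peak-to-peak homogeneity of a field map over a DSV
#'
#' Restricts the map to grid points inside the sphere and returns
#' `(max - min)/mean * 1e6` of `|B|` (or the RMS variant).  The metric is a
#' ratio, so it is invariant under global scaling of B.
#'
#' @param map a [field_map()].
#' @param diameter sphere diameter, meters.
#' @param center sphere center, meters.
#' @param metric `"peak_to_peak"` or `"rms"`.
#' @return scalar ppm.
#' @export
ppm_over_dsv <- function(map, diameter, center = c(0, 0, 0),
                         metric = c("peak_to_peak", "rms")) {
  stopifnot(inherits(map, "field_map"))
  metric <- match.arg(metric)
  pts <- grid_points(map)
  d2 <- rowSums(sweep(pts, 2, center)^2)
  sel <- d2 <= (diameter / 2)^2 + 1e-12
  if (!any(sel)) stop("no grid points inside the DSV")
  homogeneity_objective(map$B[sel, , drop = FALSE], metric = metric)
}

#' First-order spherical-harmonic fit of a field component
#'
#' Least-squares fit of `B_comp(r) = c0 + gx*x + gy*y + gz*z` over the grid
#' points inside the fit region; the degree-1 solid harmonics are exactly the
#' Cartesian coordinates, so the gradient strengths are the fitted slopes.
#' When the map metadata carries the drive current (`current_A`), the gradient
#' efficiency in mT/m/A is reported as well.
#'
#' @param map a [field_map()].
#' @param component which field component to fit: `"x"`, `"y"`, `"z"`, or
#'   `"mag"` for `|B|`; default is the map's nominal B0 axis.
#' @param diameter optional fit-region sphere diameter, meters (default: all
#'   grid points).
#' @param center fit-region center.
#' @return list with `offset` (tesla), `gradients` (tesla/m, 3-vector),
#'   `residual_rms` (tesla), and `efficiency_mT_m_A` (or `NULL`).
#' @export
fit_first_order_sh <- function(map, component = NULL, diameter = NULL,
                               center = c(0, 0, 0)) {
  stopifnot(inherits(map, "field_map"))
  if (is.null(component)) component <- map$metadata$b0_axis
  pts <- grid_points(map)
  if (!is.null(diameter)) {
    sel <- rowSums(sweep(pts, 2, center)^2) <= (diameter / 2)^2 + 1e-12
    pts <- pts[sel, , drop = FALSE]
    Bm <- map$B[sel, , drop = FALSE]
  } else Bm <- map$B
  if (nrow(pts) < 4L) stop("need at least 4 sample points for a first-order fit")
  y <- switch(component,
              x = Bm[, 1], y = Bm[, 2], z = Bm[, 3],
              mag = sqrt(rowSums(Bm^2)),
              stop("component must be 'x', 'y', 'z' or 'mag'"))
  X <- cbind(1, pts)
  qrX <- qr(X)
  if (qrX$rank < 4L)
    stop("rank-deficient sample points (coplanar grid); cannot fit gradients")
  beta <- qr.coef(qrX, y)
  res <- y - X %*% beta
  out <- list(offset = unname(beta[1]), gradients = unname(beta[2:4]),
              residual_rms = sqrt(mean(res^2)))
  cur <- map$metadata$current_A
  if (!is.null(cur) && is.finite(cur) && cur != 0)
    out$efficiency_mT_m_A <- out$gradients * 1e3 / cur
  out
}

#' Synthetic inhomogeneous field map
#'
#' A uniform B0 along the nominal axis plus a random smooth perturbation made
#' of degree 1-2 solid harmonics, scaled to a requested peak-to-peak ppm over
#' a DSV.  Emulates the long-wavelength inhomogeneity of an as-built magnet
#' (construction gaps, magnet impurities) for shimming studies; it does not
#' emulate localized defects or probe drift.
#'
#' @param b0 mean field, tesla.
#' @param ppm_target peak-to-peak inhomogeneity over the DSV, ppm.
#' @param grid grid specification (see [grid_spec()]).
#' @param dsv DSV diameter used for the scaling, meters.
#' @param orders harmonic degrees to include (subset of 1:2).
#' @param seed integer seed for the random coefficients.
#' @return a [field_map()] with the perturbation on the B0-axis component.
#' @export
synthetic_inhomogeneity_map <- function(b0 = 0.043, ppm_target = 3000,
                                        grid = grid_spec(0.11, 11L),
                                        dsv = 0.10, orders = 1:2,
                                        seed = 1L) {
  stopifnot(all(orders %in% 1:2), ppm_target >= 0)
  set.seed(seed)
  pts <- grid_points(grid)
  x <- pts[, 1]; y <- pts[, 2]; z <- pts[, 3]
  basis <- list()
  if (1 %in% orders) basis <- c(basis, list(x, y, z))
  if (2 %in% orders)
    basis <- c(basis, list(x * y, x * z, y * z, x^2 - y^2,
                           2 * z^2 - x^2 - y^2))
  # scale each basis function to unit RMS over the grid so the random mix is
  # balanced across degrees
  Bmat <- vapply(basis, function(b) b / sqrt(mean(b^2)), numeric(length(x)))
  pert <- as.numeric(Bmat %*% rnorm(ncol(Bmat)))
  B <- matrix(0, length(x), 3)
  B[, 1] <- b0
  if (ppm_target > 0 && diff(range(pert)) > 0) {
    sel <- rowSums(pts^2) <= (dsv / 2)^2 + 1e-12
    scale <- ppm_target * 1e-6 * b0 / diff(range(pert[sel]))
    B[, 1] <- b0 + pert * scale
  }
  field_map(grid$origin, grid$spacing, grid$dim, B,
            list(source = sprintf("synthetic low-order inhomogeneity (seed %d)",
                                  seed),
                 created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                 b0_axis = "x"))
}
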