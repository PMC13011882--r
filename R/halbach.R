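## Parameterized multi-ring, multi-layer Halbach array of cuboid magnets and
## genetic optimization of its geometry for B0 homogeneity.

#' Halbach array design constraints
#'
#' Geometry envelope and magnet budget of the main magnet.  Defaults are the
#' reference scanner: 990 cube magnets of 12.7 mm edge in 12 rings of 3 layers,
#' minimum inner diameter 26.54 cm, total length 35.2 cm, outer diameter
#' 39.05 cm, 11 cm target field of view, homogeneity evaluated over a 10 cm
#' diameter spherical volume (DSV).
#'
#' @param total_magnets total number of cube magnets.
#' @param n_rings number of rings along the bore.
#' @param n_layers radial layers per ring.
#' @param min_inner_diameter,total_length,outer_diameter bore envelope, meters.
#' @param magnet_edge cube edge, meters.
#' @param target_fov imaging field of view diameter, meters.
#' @param dsv_eval homogeneity evaluation DSV diameter, meters.
#' @param remanence magnet remanent flux density Br, tesla.  1.26 T is the
#'   nominal N40-grade datasheet value; the central field scales linearly
#'   with it.
#' @param design_field nominal operating field B0 of the scanner, tesla
#'   (default 43 mT).  The rest of the system -- solenoid coil tuning,
#'   gradient design, Larmor frequency -- is built for this field, so the
#'   geometry optimizer treats it as a floor on the mean bore field rather
#'   than trading field strength away for homogeneity.
#' @return an object of class `halbach_constraints`.
#' @export
halbach_constraints <- function(total_magnets = 990L, n_rings = 12L,
                                n_layers = 3L, min_inner_diameter = 0.2654,
                                total_length = 0.352, outer_diameter = 0.3905,
                                magnet_edge = 0.0127, target_fov = 0.11,
                                dsv_eval = 0.10, remanence = 1.26,
                                design_field = 0.043) {
  stopifnot(min_inner_diameter < outer_diameter, total_length > 0,
            magnet_edge > 0, total_magnets > 0, n_rings > 0, n_layers > 0,
            remanence > 0, design_field > 0)
  structure(list(total_magnets = as.integer(total_magnets),
                 n_rings = as.integer(n_rings), n_layers = as.integer(n_layers),
                 min_inner_diameter = min_inner_diameter,
                 total_length = total_length, outer_diameter = outer_diameter,
                 magnet_edge = magnet_edge, target_fov = target_fov,
                 dsv_eval = dsv_eval, remanence = remanence,
                 design_field = design_field),
            class = "halbach_constraints")
}

# feasible band for magnet center radii: half the cube diagonal clearance
# inside the envelope
.radius_band <- function(con) {
  hd <- con$magnet_edge * sqrt(2) / 2
  c(con$min_inner_diameter / 2 + hd, con$outer_diameter / 2 - hd)
}

#' Allocate magnets per ring and layer
#'
#' The magnet budget rarely divides evenly over rings and layers (990 over 12
#' rings is 82.5 per ring).  The default allocation keeps the count *equal
#' across the layers of each ring* (990 = 6 rings of 3 x 28 plus 6 rings of
#' 3 x 27, heavier rings assigned mirror-symmetrically about the center):
#' equal counts put all layers of a ring on one shared azimuth grid, so
#' radially adjacent cubes sit face-parallel and the layers can nest at a
#' radial pitch of a single cube edge -- the tight packing of the physical
#' nested ring formers, and the packing that maximizes field at the bore.
#' When the remainder cannot be spread in whole-ring multiples of
#' `n_layers`, the leftover magnets go one-per-layer to the outermost rings
#' (those rings then need the conservative diagonal clearance between
#' layers).
#'
#' @param con a [halbach_constraints()] object.
#' @return integer matrix `n_rings x n_layers` summing to `total_magnets`.
#' @export
allocate_layer_counts <- function(con) {
  nr <- con$n_rings; nl <- con$n_layers
  m <- con$total_magnets %/% (nr * nl)
  rem <- con$total_magnets - m * nr * nl
  counts <- matrix(m, nr, nl)
  # whole-ring increments of nl magnets, mirror-symmetric from the ends
  n_hi <- rem %/% nl
  hi_idx <- integer(0)
  k <- 0L
  while (length(hi_idx) < n_hi) {
    k <- k + 1L
    hi_idx <- unique(c(hi_idx, k, nr + 1L - k))
  }
  if (n_hi > 0) counts[hi_idx[seq_len(n_hi)], ] <- m + 1L
  # leftover (< nl): one magnet per layer on outer rings, innermost layer first
  left <- rem - n_hi * nl
  ring <- nr
  lay <- 1L
  while (left > 0L) {
    counts[ring, lay] <- counts[ring, lay] + 1L
    ring <- ring - 1L
    if (ring < 1L) { ring <- nr; lay <- lay + 1L }
    left <- left - 1L
  }
  storage.mode(counts) <- "integer"
  stopifnot(sum(counts) == con$total_magnets)
  counts
}

# minimum center-to-center radial pitch between layers: one edge when every
# ring has equal per-layer counts (shared azimuth grid, parallel faces),
# otherwise the cube diagonal
.layer_gap <- function(con, counts) {
  equal <- all(apply(counts, 1, function(r) length(unique(r)) == 1L))
  if (equal) con$magnet_edge else con$magnet_edge * sqrt(2)
}

#' Halbach array design
#'
#' The free geometry of the array: axial ring positions, per-layer radii, and
#' a per-ring angular offset.  Magnets on a ring sit at equally spaced
#' azimuths; the magnetization of the cube at azimuth `phi` points along
#' `(cos 2*phi, sin 2*phi, 0)` (k = 2 dipole Halbach pattern) and the cube
#' frame co-rotates with it.
#'
#' @param ring_z numeric vector of ring axial positions (meters, isocenter at
#'   0), length `n_rings`.
#' @param layer_radius numeric vector of layer radii (meters), length
#'   `n_layers`.
#' @param ring_angle_offset per-ring azimuthal offset (radians).
#' @param constraints a [halbach_constraints()] object.
#' @param layer_counts optional `n_rings x n_layers` integer matrix; default
#'   [allocate_layer_counts()].
#' @return an object of class `halbach_design`.
#' @export
halbach_design <- function(ring_z, layer_radius, ring_angle_offset = NULL,
                           constraints = halbach_constraints(),
                           layer_counts = NULL) {
  con <- constraints
  stopifnot(length(ring_z) == con$n_rings,
            length(layer_radius) == con$n_layers)
  if (is.null(ring_angle_offset)) ring_angle_offset <- rep(0, con$n_rings)
  stopifnot(length(ring_angle_offset) == con$n_rings)
  half_len <- con$total_length / 2 - con$magnet_edge / 2
  if (any(ring_z < -half_len - 1e-9 | ring_z > half_len + 1e-9))
    stop("ring_z outside [-L/2 + edge/2, L/2 - edge/2]")
  band <- .radius_band(con)
  if (any(layer_radius < band[1] - 1e-9 | layer_radius > band[2] + 1e-9))
    stop("layer_radius outside the feasible radial band")
  if (is.null(layer_counts)) layer_counts <- allocate_layer_counts(con)
  stopifnot(all(dim(layer_counts) == c(con$n_rings, con$n_layers)),
            sum(layer_counts) == con$total_magnets)
  structure(list(ring_z = as.numeric(ring_z),
                 layer_radius = as.numeric(layer_radius),
                 ring_angle_offset = as.numeric(ring_angle_offset),
                 layer_counts = layer_counts,
                 remanence = con$remanence, constraints = con),
            class = "halbach_design")
}

#' @export
print.halbach_design <- function(x, ...) {
  cat(sprintf("<halbach design> %d magnets, %d rings x %d layers\n",
              sum(x$layer_counts), length(x$ring_z), length(x$layer_radius)))
  cat("  ring z   (mm):", paste(sprintf("%.1f", x$ring_z * 1e3), collapse = " "), "\n")
  cat("  layer r  (mm):", paste(sprintf("%.1f", x$layer_radius * 1e3), collapse = " "), "\n")
  invisible(x)
}

# raw geometry of all magnets: centers, magnetization azimuth angles
.halbach_layout <- function(design) {
  con <- design$constraints
  nmag <- sum(design$layer_counts)
  centers <- matrix(0, nmag, 3)
  psi <- numeric(nmag)       # magnetization angle in the transverse plane
  ring_id <- integer(nmag)
  at <- 0L
  for (i in seq_len(con$n_rings)) {
    for (l in seq_len(con$n_layers)) {
      n <- design$layer_counts[i, l]
      if (n == 0L) next
      phi <- 2 * pi * (seq_len(n) - 1L) / n + design$ring_angle_offset[i]
      idx <- at + seq_len(n)
      centers[idx, 1] <- design$layer_radius[l] * cos(phi)
      centers[idx, 2] <- design$layer_radius[l] * sin(phi)
      centers[idx, 3] <- design$ring_z[i]
      psi[idx] <- 2 * phi
      ring_id[idx] <- i
      at <- at + n
    }
  }
  list(centers = centers, psi = psi, ring_id = ring_id)
}

# check geometric feasibility; returns character(0) or messages about
# offending pairs
.halbach_overlaps <- function(design) {
  con <- design$constraints
  e <- con$magnet_edge
  diag2 <- e * sqrt(2)
  probs <- character(0)
  # azimuthal spacing within each layer ring
  for (i in seq_len(con$n_rings)) {
    for (l in seq_len(con$n_layers)) {
      n <- design$layer_counts[i, l]
      if (n < 2L) next
      arc <- 2 * pi * design$layer_radius[l] / n
      if (arc < diag2)
        probs <- c(probs, sprintf(
          "ring %d layer %d: arc spacing %.1f mm < magnet diagonal %.1f mm",
          i, l, arc * 1e3, diag2 * 1e3))
    }
  }
  # radial separation between layers (one edge suffices for equal-count
  # rings whose layers share an azimuth grid)
  gap_r <- .layer_gap(con, design$layer_counts)
  r <- sort(design$layer_radius)
  dr <- diff(r)
  bad <- which(dr < gap_r - 1e-12)
  for (b in bad)
    probs <- c(probs, sprintf("layers at r = %.1f / %.1f mm closer than %.1f mm",
                              r[b] * 1e3, r[b + 1] * 1e3, gap_r * 1e3))
  # axial separation between rings
  z <- sort(design$ring_z)
  dz <- diff(z)
  bad <- which(dz < e - 1e-12)
  for (b in bad)
    probs <- c(probs, sprintf("rings at z = %.1f / %.1f mm closer than %.1f mm",
                              z[b] * 1e3, z[b + 1] * 1e3, e * 1e3))
  probs
}

#' Build the magnet list of a Halbach design
#'
#' Places every cube of the design and returns them as [cuboid_magnet()]
#' objects.  Overlapping magnets (azimuthal, radial or axial clearance below
#' one cube diagonal / edge) raise an error listing the offending pairs.
#'
#' @param design a [halbach_design()].
#' @return list of `cuboid_magnet`, of length `constraints$total_magnets`.
#' @export
build_halbach <- function(design) {
  stopifnot(inherits(design, "halbach_design"))
  probs <- .halbach_overlaps(design)
  if (length(probs))
    stop("overlapping magnets:\n  ", paste(probs, collapse = "\n  "))
  lay <- .halbach_layout(design)
  con <- design$constraints
  lapply(seq_len(nrow(lay$centers)), function(i) {
    psi <- lay$psi[i]
    cuboid_magnet(lay$centers[i, ], con$magnet_edge,
                  c(cos(psi), sin(psi), 0), design$remanence,
                  rotation = .rot_z(psi))
  })
}

# fast path: packed kernel matrices without building R objects
.halbach_pack <- function(design) {
  lay <- .halbach_layout(design)
  n <- nrow(lay$centers)
  cpsi <- cos(lay$psi); spsi <- sin(lay$psi)
  rot <- cbind(cpsi, -spsi, 0, spsi, cpsi, 0, 0, 0, 1)  # row-major Rz(psi)
  Jbody <- cbind(rep(design$remanence, n), 0, 0)
  list(centers = lay$centers, half = rep(design$constraints$magnet_edge / 2, n),
       rot = rot, Jbody = Jbody)
}

#' Field of a Halbach design
#'
#' @param design a [halbach_design()].
#' @param points n x 3 matrix (meters).
#' @return n x 3 matrix of B (tesla).
#' @export
halbach_field <- function(design, points) {
  pk <- .halbach_pack(design)
  cpp_field_cuboids(pk$centers, pk$half, pk$rot, pk$Jbody, .as_points(points))
}

#' Regular grid clipped to a spherical volume
#'
#' `n^3` regular grid spanning the sphere's bounding cube, restricted to points
#' inside the sphere; the default 11-point axis sampling of a DSV gives 515
#' points.
#'
#' @param diameter sphere diameter, meters.
#' @param n grid points per axis.
#' @param center sphere center.
#' @return matrix of points (m) inside the sphere.
#' @export
dsv_grid <- function(diameter, n = 11L, center = c(0, 0, 0)) {
  s <- seq(-diameter / 2, diameter / 2, length.out = n)
  g <- as.matrix(expand.grid(x = s, y = s, z = s))
  g <- g[rowSums(g^2) <= (diameter / 2)^2 + 1e-12, , drop = FALSE]
  sweep(g, 2, center, `+`)
}

#' Peak-to-peak field homogeneity in ppm
#'
#' `(max - min) / mean * 1e6` of `|B|` over the evaluation points (the usual
#' figure of merit in Halbach design); `metric = "rms"` gives `sd/mean * 1e6`.
#'
#' @param design a `halbach_design`, a list of field sources, or an n x 3
#'   matrix of B vectors already evaluated on the grid.
#' @param eval_grid m x 3 matrix of evaluation points (ignored when `design`
#'   is a matrix of fields).
#' @param metric `"peak_to_peak"` (default) or `"rms"`.
#' @return scalar ppm.
#' @export
homogeneity_objective <- function(design, eval_grid = NULL,
                                  metric = c("peak_to_peak", "rms")) {
  metric <- match.arg(metric)
  if (is.matrix(design) && ncol(design) == 3) {
    B <- design
  } else {
    if (is.null(eval_grid) || nrow(.as_points(eval_grid)) == 0L)
      stop("eval_grid is empty")
    B <- if (inherits(design, "halbach_design")) {
      halbach_field(design, eval_grid)
    } else {
      superpose(design, eval_grid)
    }
  }
  if (nrow(B) == 0L) stop("no evaluation points")
  mag <- sqrt(rowSums(B^2))
  m <- mean(mag)
  if (m == 0) stop("zero mean field; ppm undefined")
  if (metric == "peak_to_peak") (max(mag) - min(mag)) / m * 1e6
  else stats::sd(mag) / m * 1e6
}

# repair operators used by the optimizer ------------------------------------

# sort ascending and enforce minimum gaps within [lo, hi]
.space_out <- function(z, gap, lo, hi) {
  n <- length(z)
  if (lo + (n - 1) * gap > hi + 1e-12)
    stop("cannot place elements without overlap")
  z <- pmin(pmax(sort(z), lo), hi)
  for (i in seq_len(n)[-1]) z[i] <- max(z[i], z[i - 1] + gap)
  if (z[n] > hi) {
    z[n] <- hi
    for (i in rev(seq_len(n - 1))) z[i] <- min(z[i], z[i + 1] - gap)
  }
  z
}

#' Optimize a Halbach design for B0 homogeneity
#'
#' Genetic optimization of ring positions, layer radii and per-ring angular
#' offsets, minimizing the peak-to-peak inhomogeneity of `|B|` over the
#' evaluation DSV.  By default the search is restricted to mirror-symmetric
#' ring placements (pairs at `+/-z` with equal offsets), which halves the
#' search space and matches the symmetry of homogeneous solutions; set
#' `symmetric = FALSE` to search all rings independently.
#'
#' @param constraints a [halbach_constraints()].
#' @param ga a [ga_params()]; the seed is mandatory.
#' @param symmetric logical, search mirror-symmetric designs only.
#' @param eval_n grid points per axis for the evaluation DSV (default 11,
#'   i.e. 515 points over the 10 cm DSV).
#' @param polish_iter Nelder-Mead iterations used to polish the best GA
#'   individual (memetic final step; 0 disables).  The penalized field-floor
#'   objective has narrow ridges that pure crossover/mutation steps descend
#'   slowly, so a derivative-free local search finishes the job.
#' @return an object of class `halbach_optimization`: the best `design`, its
#'   `ppm` over the evaluation DSV, `mean_field_T` over the target FOV, the
#'   per-generation best-objective `trace` (non-increasing), and the GA
#'   settings used.
#' @export
optimize_halbach <- function(constraints = halbach_constraints(),
                             ga = ga_params(), symmetric = TRUE,
                             eval_n = 11L, polish_iter = 4000L) {
  con <- constraints
  if (is.null(ga$seed)) stop("ga$seed must be set")
  e <- con$magnet_edge
  half_len <- con$total_length / 2 - e / 2
  band <- .radius_band(con)
  diag2 <- e * sqrt(2)
  counts <- allocate_layer_counts(con)
  gap_r <- .layer_gap(con, counts)
  # infeasibility check before optimization
  if ((con$n_layers - 1) * gap_r > band[2] - band[1])
    stop("infeasible constraints: layers cannot fit in the radial band")
  if (con$n_rings * e > con$total_length)
    stop("infeasible constraints: rings cannot fit in the array length")
  for (l in seq_len(con$n_layers)) {
    if (max(counts[, l]) * diag2 > 2 * pi * band[1])
      stop("infeasible constraints: too many magnets per ring at minimum radius")
  }
  grid <- if (!is.null(ga$eval_grid)) ga$eval_grid else
    dsv_grid(con$dsv_eval, n = eval_n)
  # for mirror-symmetric designs |B| is even in z, so the GA objective only
  # needs the upper half of the grid; the final ppm is reported on the full grid
  obj_grid <- if (symmetric) grid[grid[, 3] >= -1e-12, , drop = FALSE] else grid
  max_off <- pi / max(counts)  # half of one azimuthal magnet spacing

  nr <- con$n_rings
  nh <- nr %/% 2L
  if (symmetric && nr %% 2L != 0L)
    stop("symmetric search requires an even number of rings")

  decode <- function(x) {
    if (symmetric) {
      zh <- .space_out(x[seq_len(nh)], e, e / 2, half_len)
      z <- c(-rev(zh), zh)
      off <- x[nh + con$n_layers + seq_len(nh)]
      offs <- c(rev(off), off)
      r <- x[nh + seq_len(con$n_layers)]
    } else {
      z <- .space_out(x[seq_len(nr)], e, -half_len, half_len)
      offs <- x[nr + con$n_layers + seq_len(nr)]
      r <- x[nr + seq_len(con$n_layers)]
    }
    halbach_design(z, r, offs, con, counts)
  }
  repair_r <- function(x) {
    ir <- (if (symmetric) nh else nr) + seq_len(con$n_layers)
    x[ir] <- .space_out(x[ir], gap_r, band[1], band[2])
    x
  }
  nz <- if (symmetric) nh else nr
  lower <- c(rep(if (symmetric) e / 2 else -half_len, nz), rep(band[1], con$n_layers),
             rep(-max_off, nz))
  upper <- c(rep(half_len, nz), rep(band[2], con$n_layers), rep(max_off, nz))
  # objective: DSV inhomogeneity, with a steep penalty when the mean bore
  # field drops below the scanner's design field (the rest of the system is
  # built for that field, so trading it away is not an acceptable optimum)
  obj <- function(x, bits) {
    d <- decode(x)
    B <- halbach_field(d, obj_grid)
    mag <- sqrt(rowSums(B^2))
    m <- mean(mag)
    ppm <- (max(mag) - min(mag)) / m * 1e6
    short <- (con$design_field - m) / con$design_field
    if (short > 0) ppm <- ppm + short * 1e8
    ppm
  }
  # seed the population with an evenly spread equal-spacing baseline
  base_z <- if (symmetric) seq(e, half_len - e, length.out = nh) else
    seq(-half_len + e, half_len - e, length.out = nr)
  base <- c(base_z, band[1] + gap_r * (seq_len(con$n_layers) - 1L),
            rep(0, nz))
  res <- ga_minimize(obj, lower, upper, n_bits = 0L, params = ga,
                     init = list(list(x = base)), repair = repair_r)
  if (polish_iter > 0) {
    # memetic polish of the GA champion; repair keeps iterates feasible
    pol <- stats::optim(res$par, function(x) obj(repair_r(pmin(pmax(x, lower),
                                                               upper)), NULL),
                        method = "Nelder-Mead",
                        control = list(maxit = polish_iter, reltol = 1e-10))
    if (pol$value < res$value) {
      res$par <- repair_r(pmin(pmax(pol$par, lower), upper))
      res$value <- pol$value
      res$trace <- c(res$trace, pol$value)
    }
    res$evaluations <- res$evaluations + pol$counts[["function"]]
  }
  best <- decode(res$par)
  fov_pts <- dsv_grid(con$target_fov, n = eval_n)
  Bf <- halbach_field(best, fov_pts)
  structure(list(design = best,
                 ppm = homogeneity_objective(best, grid),
                 mean_field_T = mean(sqrt(rowSums(Bf^2))),
                 trace = res$trace, evaluations = res$evaluations,
                 ga = ga, symmetric = symmetric, eval_grid = grid),
            class = "halbach_optimization")
}

#' @export
print.halbach_optimization <- function(x, ...) {
  cat(sprintf("<halbach optimization> %d objective evaluations\n", x$evaluations))
  cat(sprintf("  mean |B| over target FOV : %.2f mT\n", x$mean_field_T * 1e3))
  cat(sprintf("  inhomogeneity over DSV   : %.0f ppm (peak-to-peak)\n", x$ppm))
  print(x$design)
  invisible(x)
}

## JSON serialization (lengths in mm, angles in degrees, Br in tesla) --------

#' Write / read a Halbach design as JSON
#'
#' Human-oriented units: lengths in mm, angles in degrees, remanence in tesla.
#' The round trip is lossless to double precision.
#'
#' @param design a [halbach_design()].
#' @param path file path.
#' @return `read_design` returns a `halbach_design`; `write_design` its path,
#'   invisibly.
#' @export
write_design <- function(design, path) {
  con <- design$constraints
  obj <- list(
    constraints = list(total_magnets = con$total_magnets, n_rings = con$n_rings,
                       n_layers = con$n_layers,
                       min_inner_diameter_mm = con$min_inner_diameter * 1e3,
                       total_length_mm = con$total_length * 1e3,
                       outer_diameter_mm = con$outer_diameter * 1e3,
                       magnet_edge_mm = con$magnet_edge * 1e3,
                       target_fov_mm = con$target_fov * 1e3,
                       dsv_eval_mm = con$dsv_eval * 1e3,
                       remanence_T = con$remanence),
    ring_z_mm = design$ring_z * 1e3,
    layer_radius_mm = design$layer_radius * 1e3,
    ring_angle_offset_deg = design$ring_angle_offset * 180 / pi,
    layer_counts = design$layer_counts)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_design
#' @export
read_design <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cj <- obj$constraints
  con <- halbach_constraints(cj$total_magnets, cj$n_rings, cj$n_layers,
                             cj$min_inner_diameter_mm / 1e3,
                             cj$total_length_mm / 1e3,
                             cj$outer_diameter_mm / 1e3,
                             cj$magnet_edge_mm / 1e3,
                             cj$target_fov_mm / 1e3, cj$dsv_eval_mm / 1e3,
                             cj$remanence_T)
  halbach_design(obj$ring_z_mm / 1e3, obj$layer_radius_mm / 1e3,
                 obj$ring_angle_offset_deg * pi / 180, con,
                 matrix(as.integer(obj$layer_counts), con$n_rings, con$n_layers))
}
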