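## Passive shim (small cube magnets on two cylindrical sleeves, placement
## found by genetic optimization) and active shim (30 loop coils, currents
## found by bounded ridge least squares), both driven by a measured or
## simulated field map.

#' Passive shim constraints
#'
#' Geometry of the two shim sleeves that sit on either side of the RF coil:
#' 3 mm cube magnets in rings on a cylinder of 66.5 mm radius, 22 rings of 25
#' positions in total, the two holders fixed 4 cm and 23.5 cm from the front
#' face of the magnet.
#'
#' @param sleeve_radius cylinder radius carrying the shim cubes, meters.
#' @param n_rings total number of shim rings across both holders.
#' @param magnets_per_ring candidate positions per ring.
#' @param shim_edge cube edge, meters.
#' @param holder_z axial positions of the two holder centers measured from
#'   the front face of the magnet, meters.
#' @param holder_span axial extent of each holder within which its rings may
#'   be placed, meters.
#' @param magnet_length total length of the main magnet (to convert
#'   holder positions to isocenter coordinates), meters.
#' @param remanence shim magnet Br, tesla.
#' @param rings_split `"total"` (default): `n_rings` is the total across the
#'   two holders, split evenly; `"per_holder"`: each holder carries `n_rings`.
#' @return object of class `passive_shim_constraints`.
#' @export
passive_shim_constraints <- function(sleeve_radius = 0.0665, n_rings = 22L,
                                     magnets_per_ring = 25L,
                                     shim_edge = 0.003,
                                     holder_z = c(0.04, 0.235),
                                     holder_span = 0.07,
                                     magnet_length = 0.352,
                                     remanence = 1.26,
                                     rings_split = c("total", "per_holder")) {
  rings_split <- match.arg(rings_split)
  stopifnot(n_rings >= 1L, magnets_per_ring >= 1L, sleeve_radius > 0,
            shim_edge > 0, length(holder_z) == 2L, remanence > 0)
  n_total <- if (rings_split == "total") as.integer(n_rings)
             else 2L * as.integer(n_rings)
  arc <- 2 * pi * sleeve_radius / magnets_per_ring
  if (arc < shim_edge * sqrt(2))
    stop("magnets_per_ring too large for the sleeve radius")
  per_holder <- c(ceiling(n_total / 2), floor(n_total / 2))
  if (max(per_holder) * shim_edge > holder_span)
    stop("holder_span too small for the requested rings")
  structure(list(sleeve_radius = sleeve_radius, n_rings = n_total,
                 rings_per_holder = as.integer(per_holder),
                 magnets_per_ring = as.integer(magnets_per_ring),
                 shim_edge = shim_edge,
                 holder_center_z = holder_z - magnet_length / 2,
                 holder_span = holder_span,
                 remanence = remanence, rings_split = rings_split),
            class = "passive_shim_constraints")
}

#' Passive shim solution
#'
#' Ring axial positions, per-ring rotations and the binary decision of which
#' candidate positions carry a magnet.
#'
#' @param ring_z ring axial positions, meters (isocenter coordinates).
#' @param ring_rotation per-ring azimuthal rotation, radians.
#' @param include_mask `n_rings x magnets_per_ring` 0/1 matrix.
#' @param constraints a [passive_shim_constraints()].
#' @param ring_flip optional 0/1 vector, one per ring: 1 reverses the
#'   magnetization of every cube on that ring.  Reversed rings *subtract*
#'   field, which is what makes z-odd error harmonics correctable from two
#'   asymmetrically placed holders.
#' @return object of class `passive_shim_solution`.
#' @export
passive_shim_solution <- function(ring_z, ring_rotation, include_mask,
                                  constraints, ring_flip = NULL) {
  con <- constraints
  if (is.null(ring_flip)) ring_flip <- rep(0L, con$n_rings)
  stopifnot(length(ring_z) == con$n_rings,
            length(ring_rotation) == con$n_rings,
            length(ring_flip) == con$n_rings,
            all(dim(include_mask) == c(con$n_rings, con$magnets_per_ring)))
  lo <- con$holder_center_z - con$holder_span / 2
  hi <- con$holder_center_z + con$holder_span / 2
  ok <- vapply(ring_z, function(z)
    any(z >= lo - 1e-9 & z <= hi + 1e-9), TRUE)
  if (!all(ok)) stop("ring_z outside the holder extents")
  mask <- matrix(as.integer(include_mask != 0), con$n_rings,
                 con$magnets_per_ring)
  structure(list(ring_z = as.numeric(ring_z),
                 ring_rotation = as.numeric(ring_rotation),
                 include_mask = mask,
                 ring_flip = as.integer(ring_flip != 0),
                 constraints = con),
            class = "passive_shim_solution")
}

#' @export
print.passive_shim_solution <- function(x, ...) {
  cat(sprintf("<passive shim> %d of %d magnets placed on %d rings (%d reversed)\n",
              sum(x$include_mask), length(x$include_mask),
              x$constraints$n_rings, sum(x$ring_flip)))
  invisible(x)
}

# packed kernel matrices for the included shim cubes (k = 2 Halbach
# magnetization convention at each cube's azimuth)
.shim_pack <- function(solution) {
  con <- solution$constraints
  npos <- con$magnets_per_ring
  rows <- which(solution$include_mask != 0, arr.ind = TRUE)
  n <- nrow(rows)
  if (n == 0L) return(NULL)
  phi <- 2 * pi * (rows[, 2] - 1L) / npos + solution$ring_rotation[rows[, 1]]
  centers <- cbind(con$sleeve_radius * cos(phi),
                   con$sleeve_radius * sin(phi),
                   solution$ring_z[rows[, 1]])
  psi <- 2 * phi
  rot <- cbind(cos(psi), -sin(psi), 0, sin(psi), cos(psi), 0, 0, 0, 1)
  sgn <- ifelse(solution$ring_flip[rows[, 1]] == 1L, -1, 1)
  list(centers = centers, half = rep(con$shim_edge / 2, n), rot = rot,
       Jbody = cbind(sgn * con$remanence, 0, 0))
}

#' Field of a passive shim solution
#'
#' Superposed field of all included shim cubes; each cube is magnetized along
#' the k = 2 Halbach direction of its azimuth (so a fully populated ring adds
#' a nearly uniform transverse field and its low-order gradients correct the
#' map).  The empty mask gives the zero field.
#'
#' @param solution a [passive_shim_solution()].
#' @param points n x 3 matrix (meters).
#' @return n x 3 matrix of B (tesla).
#' @export
shim_field <- function(solution, points) {
  stopifnot(inherits(solution, "passive_shim_solution"))
  points <- .as_points(points)
  pk <- .shim_pack(solution)
  if (is.null(pk)) return(matrix(0, nrow(points), 3))
  cpp_field_cuboids(pk$centers, pk$half, pk$rot, pk$Jbody, points)
}

#' Magnet list of a passive shim solution
#'
#' The included shim cubes as [cuboid_magnet()] objects (one per set mask
#' bit); `shim_field()` is the batched equivalent.
#'
#' @param solution a [passive_shim_solution()].
#' @return list of `cuboid_magnet`.
#' @export
shim_magnets <- function(solution) {
  pk <- .shim_pack(solution)
  if (is.null(pk)) return(list())
  con <- solution$constraints
  lapply(seq_len(nrow(pk$centers)), function(i) {
    R <- matrix(pk$rot[i, ], 3, 3, byrow = TRUE)
    s <- sign(pk$Jbody[i, 1])
    cuboid_magnet(pk$centers[i, ], con$shim_edge, as.numeric(s * R[, 1]),
                  con$remanence, rotation = R)
  })
}

#' Optimize passive shim placement against a field map
#'
#' Genetic optimization (mixed continuous + binary encoding) of ring
#' positions, rotations and the per-position inclusion mask, minimizing the
#' peak-to-peak ppm of `|B_map + B_shim|` over the DSV.  The empty mask is
#' injected into the initial population, so with elitist selection the
#' reported shimmed ppm can never exceed the unshimmed ppm.
#'
#' @param map a [field_map()] covering the DSV.
#' @param constraints a [passive_shim_constraints()].
#' @param ga a [ga_params()]; seed mandatory.  The default budget is larger
#'   than for the main-magnet search because the mask adds hundreds of binary
#'   genes.
#' @param dsv DSV diameter for the objective, meters.
#' @param allow_flip also optimize a per-ring polarity flip bit (default
#'   `TRUE`).  Without it the shim can only add field of one sign, which
#'   leaves z-odd error harmonics (and, with two one-sided holders, much of
#'   the z-even ones) structurally uncorrectable.
#' @return object of class `passive_shim_fit`: `solution`, `ppm_before`,
#'   `ppm_after`, `improvement_pct`, `trace`.
#' @export
optimize_passive_shim <- function(map, constraints = passive_shim_constraints(),
                                  ga = ga_params(population = 60L,
                                                 generations = 250L,
                                                 patience = 60L),
                                  dsv = 0.10, allow_flip = TRUE) {
  stopifnot(inherits(map, "field_map"),
            inherits(constraints, "passive_shim_constraints"))
  con <- constraints
  if (is.null(ga$seed)) stop("ga$seed must be set")
  pts_all <- grid_points(map)
  sel <- rowSums(pts_all^2) <= (dsv / 2)^2 + 1e-12
  if (!any(sel)) stop("field map does not cover the DSV")
  ext <- apply(abs(pts_all), 2, max)
  if (any(ext < dsv / 2 - 1e-9)) stop("field map does not cover the DSV")
  pts <- pts_all[sel, , drop = FALSE]
  Bmap <- map$B[sel, , drop = FALSE]
  ppm_before <- homogeneity_objective(Bmap)

  nr <- con$n_rings
  npos <- con$magnets_per_ring
  nb <- nr * npos
  n_bits <- nb + if (allow_flip) nr else 0L
  holder_of <- rep(1:2, con$rings_per_holder)
  lo <- con$holder_center_z[holder_of] - con$holder_span / 2
  hi <- con$holder_center_z[holder_of] + con$holder_span / 2
  max_rot <- pi / npos
  lower <- c(lo, rep(-max_rot, nr))
  upper <- c(hi, rep(max_rot, nr))
  repair <- function(x) {
    for (h in 1:2) {
      i <- which(holder_of == h)
      x[i] <- .space_out(x[i], con$shim_edge, lo[i[1]], hi[i[1]])
    }
    x
  }
  decode <- function(x, bits) {
    passive_shim_solution(x[seq_len(nr)], x[nr + seq_len(nr)],
                          matrix(bits[seq_len(nb)], nr, npos), con,
                          ring_flip = if (allow_flip) bits[nb + seq_len(nr)]
                                      else NULL)
  }
  obj <- function(x, bits) {
    if (!any(bits[seq_len(nb)])) return(ppm_before)
    sol <- decode(x, bits)
    homogeneity_objective(Bmap + shim_field(sol, pts))
  }
  # deterministic baseline individual: rings evenly spread in their holders,
  # zero rotation, empty mask (guarantees shimmed <= unshimmed under elitism)
  base_z <- repair(unlist(lapply(1:2, function(h) {
    i <- which(holder_of == h)
    seq(lo[i[1]], hi[i[1]], length.out = length(i) + 2L)[-c(1L, length(i) + 2L)]
  })))
  init <- list(list(x = c(base_z, rep(0, nr)), bits = rep(0L, n_bits)))
  res <- ga_minimize(obj, lower, upper, n_bits = n_bits, params = ga,
                     init = init, repair = repair)
  sol <- decode(res$par, res$bits)
  ppm_after <- min(res$value, ppm_before)
  impr <- if (ppm_before > 0) 100 * (ppm_before - ppm_after) / ppm_before else 0
  structure(list(solution = sol, ppm_before = ppm_before,
                 ppm_after = ppm_after,
                 improvement_pct = impr,
                 trace = res$trace, evaluations = res$evaluations, ga = ga,
                 dsv = dsv),
            class = "passive_shim_fit")
}

#' @export
print.passive_shim_fit <- function(x, ...) {
  cat(sprintf("<passive shim fit> %.0f -> %.0f ppm (%.1f%% improvement)\n",
              x$ppm_before, x$ppm_after, x$improvement_pct))
  print(x$solution)
  invisible(x)
}

## Active shim ---------------------------------------------------------------

#' Active shim coil array
#'
#' Loop coils mounted on a cylindrical tube around the bore; the default is
#' 30 coils of 15 turns and 35 mm diameter on a 152 mm outer-diameter tube,
#' laid out as 5 rings of 6 equally spaced coils (the layout is a free
#' choice; only the coil count and geometry are fixed by the hardware).
#' Coil normals point radially.
#'
#' @param tube_radius cylinder radius, meters.
#' @param n_axial,n_azimuthal layout: rings along the tube x coils per ring.
#' @param coil_radius loop radius, meters.
#' @param turns turns per coil.
#' @param axial_span axial extent of the coil centers, meters.
#' @param current_limit maximum magnitude per-coil current, amperes.
#' @return object of class `active_shim_array` (list with `coils`,
#'   `current_limit`).
#' @export
active_shim_array <- function(tube_radius = 0.076, n_axial = 5L,
                              n_azimuthal = 6L, coil_radius = 0.0175,
                              turns = 15L, axial_span = 0.20,
                              current_limit = 1) {
  zs <- if (n_axial == 1L) 0 else
    seq(-axial_span / 2, axial_span / 2, length.out = n_axial)
  if (n_axial > 1L && diff(zs)[1] < 2 * coil_radius)
    stop("axial_span too small: coils overlap along the tube")
  if (2 * pi * tube_radius / n_azimuthal < 2 * coil_radius)
    stop("too many coils per ring: coils overlap azimuthally")
  coils <- list()
  for (iz in seq_len(n_axial)) {
    for (ia in seq_len(n_azimuthal)) {
      # stagger alternate rings by half a spacing
      phi <- 2 * pi * (ia - 1L + 0.5 * (iz %% 2L)) / n_azimuthal
      nrm <- c(cos(phi), sin(phi), 0)
      coils[[length(coils) + 1L]] <-
        loop_coil(tube_radius * nrm, nrm, coil_radius, turns)
    }
  }
  structure(list(coils = coils, current_limit = current_limit,
                 tube_radius = tube_radius),
            class = "active_shim_array")
}

#' Solve active shim currents for a field map
#'
#' Bounded ridge least squares: precomputes the unit-current B0-axis component
#' of every coil on the map grid inside the DSV and solves
#' `min || d + A c ||^2 + lambda ||c||^2` subject to `|c_i| <= current_limit`,
#' where `d` is the centered B0-axis component of the map (the mean level is a
#' free offset: shimming corrects variation, not the absolute field).
#' `lambda = NULL` picks the corner of the L-curve over a log grid.
#'
#' @param map a [field_map()].
#' @param array an [active_shim_array()].
#' @param lambda ridge parameter (>= 0), or `NULL` for the L-curve choice.
#' @param dsv DSV diameter, meters.
#' @return object of class `active_shim_fit`: `currents` (amperes),
#'   `ppm_before`, `ppm_after`, `lambda`, `basis` (the coil response matrix).
#' @export
solve_active_shim <- function(map, array = active_shim_array(), lambda = NULL,
                              dsv = 0.10) {
  stopifnot(inherits(map, "field_map"), inherits(array, "active_shim_array"))
  pts_all <- grid_points(map)
  sel <- rowSums(pts_all^2) <= (dsv / 2)^2 + 1e-12
  if (!any(sel)) stop("field map does not cover the DSV")
  pts <- pts_all[sel, , drop = FALSE]
  Bmap <- map$B[sel, , drop = FALSE]
  comp <- match(map$metadata$b0_axis, c("x", "y", "z"))
  if (is.na(comp)) comp <- 1L
  nc <- length(array$coils)
  # unit-current basis: full vector response per coil (component `comp` is
  # fitted; all components are used for the ppm report)
  basis_full <- lapply(array$coils, function(cl) loop_field(cl, pts))
  A <- vapply(basis_full, function(b) b[, comp], numeric(nrow(pts)))
  d <- Bmap[, comp]
  A_c <- sweep(A, 2, colMeans(A))
  d_c <- d - mean(d)
  if (is.null(lambda)) lambda <- .l_curve_lambda(A_c, d_c)
  if (lambda == 0) {
    cn <- tryCatch(kappa(crossprod(A_c), exact = FALSE), error = function(e) Inf)
    if (!is.finite(cn) || cn > 1e12)
      stop("coil basis is numerically singular; use regularization (lambda > 0)")
  }
  AtA <- crossprod(A_c) + lambda * diag(nc)
  Atd <- crossprod(A_c, d_c)
  # scale the quadratic to O(1) so the optimizer's tolerances are meaningful
  # for tesla-scale residuals
  s2 <- max(sum(d_c^2), .Machine$double.xmin)
  fn <- function(c_) (sum((d_c + A_c %*% c_)^2) + lambda * sum(c_^2)) / s2
  gr <- function(c_) 2 * as.numeric(AtA %*% c_ + Atd) / s2
  o <- stats::optim(rep(0, nc), fn, gr, method = "L-BFGS-B",
                    lower = rep(-array$current_limit, nc),
                    upper = rep(array$current_limit, nc),
                    control = list(maxit = 1000, factr = 1e1, pgtol = 1e-12))
  currents <- o$par
  ppm_before <- homogeneity_objective(Bmap)
  Bshim <- matrix(0, nrow(pts), 3)
  for (i in seq_len(nc))
    if (currents[i] != 0) Bshim <- Bshim + currents[i] * basis_full[[i]]
  ppm_after <- homogeneity_objective(Bmap + Bshim)
  if (ppm_after > ppm_before) {  # zero currents are always feasible
    currents <- rep(0, nc)
    ppm_after <- ppm_before
  }
  structure(list(currents = currents, ppm_before = ppm_before,
                 ppm_after = ppm_after, lambda = lambda,
                 residual_rms = sqrt(mean((d_c + A_c %*% currents)^2)),
                 basis = A, dsv = dsv),
            class = "active_shim_fit")
}

#' @export
print.active_shim_fit <- function(x, ...) {
  cat(sprintf("<active shim fit> %.0f -> %.0f ppm, lambda %.3g, max |I| %.3f A\n",
              x$ppm_before, x$ppm_after, x$lambda, max(abs(x$currents))))
  invisible(x)
}

# L-curve corner: maximize curvature of (log residual norm, log solution
# norm) over a log-spaced lambda grid
.l_curve_lambda <- function(A, d, grid = 10^seq(-14, -2, length.out = 25)) {
  sv <- svd(A)
  uy <- crossprod(sv$u, d)
  pts <- t(vapply(grid, function(l) {
    f <- sv$d / (sv$d^2 + l)
    c_ <- sv$v %*% (f * uy)
    r <- d - A %*% c_
    c(log(sqrt(sum(r^2)) + 1e-300), log(sqrt(sum(c_^2)) + 1e-300))
  }, numeric(2)))
  n <- nrow(pts)
  curv <- rep(-Inf, n)
  for (i in 2:(n - 1)) {
    a <- pts[i - 1, ]; b <- pts[i, ]; c_ <- pts[i + 1, ]
    ab <- b - a; bc <- c_ - b
    cross <- ab[1] * bc[2] - ab[2] * bc[1]
    denom <- sqrt(sum(ab^2)) * sqrt(sum(bc^2)) * sqrt(sum((c_ - a)^2))
    if (denom > 0) curv[i] <- abs(cross) / denom
  }
  grid[which.max(curv)]
}
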