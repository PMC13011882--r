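## Analytic magnetostatics: uniformly magnetized cuboid, circular loop coil,
## superposition, and slow numerical oracles used for validation.

.unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n == 0) stop("zero-length direction vector")
  v / n
}

.as_points <- function(points) {
  if (is.numeric(points) && is.null(dim(points))) {
    if (length(points) != 3L) stop("a single point must have 3 components")
    points <- matrix(points, 1L, 3L)
  }
  points <- as.matrix(points)
  if (ncol(points) != 3L) stop("points must be an n x 3 matrix (meters)")
  storage.mode(points) <- "double"
  points
}

# rotation matrix (body -> world) whose first column is the unit vector `x`;
# completion of the frame is arbitrary but deterministic
.frame_from_x <- function(x) {
  x <- .unit(x)
  ref <- if (abs(x[3]) < 0.9) c(0, 0, 1) else c(0, 1, 0)
  y <- .unit(ref - sum(ref * x) * x)
  z <- c(x[2] * y[3] - x[3] * y[2],
         x[3] * y[1] - x[1] * y[3],
         x[1] * y[2] - x[2] * y[1])
  cbind(x, y, z, deparse.level = 0)
}

.rot_z <- function(a) {
  matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
}

#' Cuboid permanent magnet
#'
#' A uniformly magnetized cube, the building block of both the main Halbach
#' array (12.7 mm edge) and the passive shim trays (3 mm edge).
#'
#' @param center 3-vector, center position in meters.
#' @param edge edge length in meters.
#' @param magnetization_dir unit 3-vector, direction of magnetization in the
#'   world frame.
#' @param remanence remanent flux density Br in tesla (1.26 T for nominal
#'   N40-grade material).
#' @param rotation optional 3x3 rotation matrix (body to world) fixing the
#'   orientation of the cube itself.  By default the cube co-rotates with its
#'   magnetization: the body x-axis is aligned with `magnetization_dir`.
#' @return an object of class `cuboid_magnet`.
#' @examples
#' m <- cuboid_magnet(c(0, 0, 0), 0.0127, c(1, 0, 0), 1.26)
#' cuboid_field(m, c(0.1, 0, 0))
#' @export
cuboid_magnet <- function(center, edge, magnetization_dir, remanence,
                          rotation = NULL) {
  stopifnot(length(center) == 3L, is.finite(center))
  if (!is.numeric(edge) || length(edge) != 1L || edge <= 0)
    stop("edge must be a positive scalar (meters)")
  if (!is.numeric(remanence) || length(remanence) != 1L || remanence <= 0)
    stop("remanence must be a positive scalar (tesla)")
  nd <- sqrt(sum(magnetization_dir^2))
  if (abs(nd - 1) > 1e-9)
    stop("magnetization_dir must be a unit vector (|v| = 1 within 1e-9)")
  if (is.null(rotation)) {
    rotation <- .frame_from_x(magnetization_dir)
  } else {
    rotation <- as.matrix(rotation)
    stopifnot(all(dim(rotation) == c(3L, 3L)))
    if (max(abs(crossprod(rotation) - diag(3))) > 1e-8)
      stop("rotation must be orthonormal")
  }
  structure(list(center = as.numeric(center), edge = edge,
                 magnetization_dir = as.numeric(magnetization_dir),
                 remanence = remanence, rotation = rotation),
            class = "cuboid_magnet")
}

#' @export
print.cuboid_magnet <- function(x, ...) {
  cat(sprintf("<cuboid magnet> edge %.1f mm, Br %.2f T, center (%.1f, %.1f, %.1f) mm\n",
              x$edge * 1e3, x$remanence,
              x$center[1] * 1e3, x$center[2] * 1e3, x$center[3] * 1e3))
  invisible(x)
}

# pack a list of cuboid_magnet into the matrices the C++ kernel consumes
.pack_cuboids <- function(magnets) {
  M <- length(magnets)
  centers <- matrix(0, M, 3)
  half <- numeric(M)
  rot <- matrix(0, M, 9)
  Jbody <- matrix(0, M, 3)
  for (i in seq_len(M)) {
    m <- magnets[[i]]
    centers[i, ] <- m$center
    half[i] <- m$edge / 2
    rot[i, ] <- as.numeric(t(m$rotation))  # row-major
    Jbody[i, ] <- as.numeric(crossprod(m$rotation,
                                       m$remanence * m$magnetization_dir))
  }
  list(centers = centers, half = half, rot = rot, Jbody = Jbody)
}

#' Field of one or more cuboid magnets
#'
#' Closed-form field of uniformly magnetized rectangular prisms (charged-surface
#' solution), valid both outside and inside the magnet volume; inside, the
#' returned field is the full flux density `B = mu0*(H + M)`.  Points exactly on
#' a face or edge lie on the singular locus of the closed form and return
#' non-finite components; offset such points by any small amount.
#'
#' @param magnet a `cuboid_magnet`, or a list of them (fields are superposed).
#' @param points n x 3 matrix of evaluation points (meters), or a 3-vector.
#' @return n x 3 matrix of B vectors in tesla.
#' @export
cuboid_field <- function(magnet, points) {
  if (inherits(magnet, "cuboid_magnet")) magnet <- list(magnet)
  stopifnot(all(vapply(magnet, inherits, TRUE, "cuboid_magnet")))
  points <- .as_points(points)
  pk <- .pack_cuboids(magnet)
  cpp_field_cuboids(pk$centers, pk$half, pk$rot, pk$Jbody, points)
}

#' Brute-force numerical cuboid field (validation oracle)
#'
#' Midpoint-rule quadrature of the magnetic surface charge on the two faces
#' perpendicular to each magnetization component, with the interior
#' magnetization term added inside the volume.  Converges to [cuboid_field()]
#' as `n_subdiv` grows; used only to validate the closed form.
#'
#' @param magnet a `cuboid_magnet`.
#' @param point single 3-vector (meters).
#' @param n_subdiv quadrature subdivisions per face edge (>= 2).
#' @return B 3-vector in tesla.
#' @export
cuboid_field_numeric <- function(magnet, point, n_subdiv = 64) {
  stopifnot(inherits(magnet, "cuboid_magnet"), n_subdiv >= 2)
  point <- as.numeric(point)
  stopifnot(length(point) == 3L)
  h <- magnet$edge / 2
  R <- magnet$rotation
  q <- as.numeric(crossprod(R, point - magnet$center))
  Jb <- as.numeric(crossprod(R, magnet$remanence * magnet$magnetization_dir))
  s <- (seq_len(n_subdiv) - 0.5) / n_subdiv * 2 * h - h
  g <- as.matrix(expand.grid(a = s, b = s))
  dA <- (2 * h / n_subdiv)^2
  Hb <- c(0, 0, 0)
  for (ax in 1:3) {
    if (Jb[ax] == 0) next
    o1 <- (ax %% 3) + 1L; o2 <- (o1 %% 3) + 1L
    for (sgn in c(1, -1)) {
      src <- matrix(0, nrow(g), 3)
      src[, ax] <- sgn * h
      src[, o1] <- g[, 1]
      src[, o2] <- g[, 2]
      d <- cbind(q[1] - src[, 1], q[2] - src[, 2], q[3] - src[, 3])
      r3 <- (rowSums(d^2))^1.5
      Hb <- Hb + sgn * Jb[ax] / (4 * pi) * colSums(d / r3) * dA
    }
  }
  if (all(abs(q) < h)) Hb <- Hb + Jb
  as.numeric(R %*% Hb)
}

#' Point-dipole field
#'
#' Field of an ideal magnetic dipole; the far-field limit of any magnet.
#'
#' @param moment 3-vector, magnetic moment in A m^2.
#' @param center dipole position, meters.
#' @param points n x 3 evaluation points.
#' @return n x 3 matrix of B vectors in tesla.
#' @export
dipole_field <- function(moment, center, points) {
  points <- .as_points(points)
  d <- sweep(points, 2, center)
  r <- sqrt(rowSums(d^2))
  rhat <- d / r
  mdotr <- as.numeric(rhat %*% moment)
  B <- (3 * rhat * mdotr - matrix(moment, nrow(points), 3, byrow = TRUE)) /
    r^3 * MU0 / (4 * pi)
  B
}

#' Circular loop coil
#'
#' A thin multi-turn circular loop, the element of the active-shim array
#' (30 coils of 15 turns, 35 mm diameter in the reference design).
#'
#' @param center 3-vector, loop center in meters.
#' @param normal unit 3-vector, loop axis.
#' @param radius loop radius in meters.
#' @param turns integer number of turns (>= 1); the filament approximation
#'   multiplies the single-loop field by `turns`.
#' @return an object of class `loop_coil`.
#' @export
loop_coil <- function(center, normal, radius, turns = 1L) {
  stopifnot(length(center) == 3L, is.finite(center))
  if (radius <= 0) stop("radius must be positive")
  if (turns < 1) stop("turns must be >= 1")
  structure(list(center = as.numeric(center), normal = .unit(normal),
                 radius = radius, turns = as.integer(turns)),
            class = "loop_coil")
}

#' Field of a circular loop coil
#'
#' Exact off-axis field of a circular filament via complete elliptic integrals,
#' scaled by the number of turns and the drive current.  On the axis this
#' reduces to `mu0 * turns * I * R^2 / (2 (R^2 + z^2)^(3/2))`.  Points on the
#' filament itself are singular and raise an error.
#'
#' @param coil a `loop_coil`.
#' @param points n x 3 matrix (meters) or 3-vector.
#' @param current drive current in amperes (default 1: field per ampere).
#' @return n x 3 matrix of B vectors in tesla.
#' @export
loop_field <- function(coil, points, current = 1) {
  stopifnot(inherits(coil, "loop_coil"))
  points <- .as_points(points)
  R <- .frame_from_x(coil$normal)  # body x = axis
  q <- sweep(points, 2, coil$center) %*% R  # body coords, axis = col 1
  z <- q[, 1]
  rho <- sqrt(q[, 2]^2 + q[, 3]^2)
  a <- coil$radius
  on_wire <- abs(rho - a) < 1e-12 & abs(z) < 1e-12
  if (any(on_wire)) stop("field point lies on the coil filament")
  I <- current * coil$turns
  Bz <- numeric(length(z))
  Brho <- numeric(length(z))
  ax <- rho < 1e-12
  if (any(ax)) {
    Bz[ax] <- MU0 * I * a^2 / (2 * (a^2 + z[ax]^2)^1.5)
  }
  if (any(!ax)) {
    zz <- z[!ax]; rr <- rho[!ax]
    Q <- (a + rr)^2 + zz^2
    m <- 4 * a * rr / Q
    ke <- pracma::ellipke(m)
    K <- ke$k; E <- ke$e
    den <- (a - rr)^2 + zz^2
    Bz[!ax] <- MU0 * I / (2 * pi * sqrt(Q)) *
      (K + (a^2 - rr^2 - zz^2) / den * E)
    Brho[!ax] <- MU0 * I * zz / (2 * pi * rr * sqrt(Q)) *
      (-K + (a^2 + rr^2 + zz^2) / den * E)
  }
  # back to world frame
  rhohat <- q[, 2:3, drop = FALSE]
  nr <- sqrt(rowSums(rhohat^2))
  nr[nr < 1e-12] <- 1
  rhohat <- rhohat / nr
  Bbody <- cbind(Bz, Brho * rhohat[, 1], Brho * rhohat[, 2])
  Bbody %*% t(R)
}

#' Biot-Savart polygonal-loop field (validation oracle)
#'
#' Discretizes the loop into straight segments and sums the exact finite-wire
#' Biot-Savart contribution of each; converges to [loop_field()] as `n_seg`
#' grows.
#'
#' @param coil a `loop_coil`.
#' @param points n x 3 matrix (meters).
#' @param current amperes.
#' @param n_seg number of polygon segments.
#' @return n x 3 matrix of B vectors in tesla.
#' @export
loop_field_numeric <- function(coil, points, current = 1, n_seg = 720) {
  stopifnot(inherits(coil, "loop_coil"), n_seg >= 8)
  points <- .as_points(points)
  R <- .frame_from_x(coil$normal)
  th <- seq(0, 2 * pi, length.out = n_seg + 1)
  verts <- cbind(0, coil$radius * cos(th), coil$radius * sin(th)) %*% t(R)
  verts <- sweep(verts, 2, coil$center, `+`)
  I <- current * coil$turns
  B <- matrix(0, nrow(points), 3)
  for (s in seq_len(n_seg)) {
    A <- verts[s, ]; Bv <- verts[s + 1, ]
    L2 <- sum((Bv - A)^2)
    r1 <- sweep(points, 2, A, `-`)
    r2 <- sweep(points, 2, Bv, `-`)
    n1 <- sqrt(rowSums(r1^2)); n2 <- sqrt(rowSums(r2^2))
    cr <- cbind(r1[, 2] * r2[, 3] - r1[, 3] * r2[, 2],
                r1[, 3] * r2[, 1] - r1[, 1] * r2[, 3],
                r1[, 1] * r2[, 2] - r1[, 2] * r2[, 1])
    denom <- n1 * n2 * ((n1 + n2)^2 - L2)
    B <- B + MU0 * I / (4 * pi) * 2 * (n1 + n2) / denom * cr
  }
  B
}

#' Superpose the fields of many sources
#'
#' Linear superposition of cuboid magnets and loop coils.  An empty source list
#' returns the zero field.  Cuboids are batched through one vectorized kernel
#' call, so per-source and batched evaluation agree exactly.
#'
#' @param sources list of `cuboid_magnet` / `loop_coil` objects.  Loop coils
#'   are evaluated at the currents in `currents` (default 1 A each).
#' @param points n x 3 matrix (meters) or a 3-vector.
#' @param currents optional numeric vector of drive currents, one per loop coil
#'   in `sources` (in order).
#' @return n x 3 matrix of B vectors in tesla.
#' @export
superpose <- function(sources, points, currents = NULL) {
  points <- .as_points(points)
  B <- matrix(0, nrow(points), 3)
  if (length(sources) == 0L) return(B)
  is_cub <- vapply(sources, inherits, TRUE, "cuboid_magnet")
  is_coil <- vapply(sources, inherits, TRUE, "loop_coil")
  if (!all(is_cub | is_coil))
    stop("sources must be cuboid_magnet or loop_coil objects")
  if (any(is_cub)) B <- B + cuboid_field(sources[is_cub], points)
  coils <- sources[is_coil]
  if (length(coils)) {
    if (is.null(currents)) currents <- rep(1, length(coils))
    stopifnot(length(currents) == length(coils))
    for (i in seq_along(coils)) {
      if (currents[i] != 0)
        B <- B + loop_field(coils[[i]], points, current = currents[i])
    }
  }
  B
}
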