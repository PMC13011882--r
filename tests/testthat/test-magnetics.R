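# analytic cuboid / loop fields against independent numerical oracles

test_that("cuboid field validates inputs and handles degenerate magnets", {
  expect_error(cuboid_magnet(c(0, 0, 0), -1, c(1, 0, 0), 1.26), "edge")
  expect_error(cuboid_magnet(c(0, 0, 0), 0.01, c(1, 1, 0), 1.26), "unit")
  expect_error(cuboid_magnet(c(0, 0, 0), 0.01, c(1, 0, 0), 0), "remanence")
  # remanence ~ 0 limit: field scales linearly with Br, so tiny Br -> tiny field
  m <- cuboid_magnet(c(0, 0, 0), 0.0127, c(0, 0, 1), 1e-12)
  B <- cuboid_field(m, c(0.03, 0.01, 0.02))
  expect_lt(max(abs(B)), 1e-12)
})

test_that("far field matches the point-dipole formula", {
  Br <- 1.26; edge <- 0.0127
  m <- main_cube(dir = c(0, 0, 1), Br = Br)
  mom <- Br / mu0 * edge^3
  r <- 0.5
  B <- cuboid_field(m, c(0, 0, r))
  expect_equal(B[3], mu0 * 2 * mom / (4 * pi * r^3), tolerance = 1e-3)
  expect_lt(max(abs(B[1:2])), 1e-12)
  # transverse magnetization: same moment along x
  mx <- main_cube(dir = c(1, 0, 0))
  Bx <- cuboid_field(mx, c(r, 0, 0))
  expect_equal(Bx[1], mu0 * 2 * mom / (4 * pi * r^3), tolerance = 1e-3)
})

test_that("analytic cuboid field matches the surface-charge oracle", {
  m <- main_cube(dir = c(0, 0, 1))
  # near-field point 20 mm from a face
  p <- c(0, 0, 0.0127 / 2 + 0.020)
  expect_equal(as.numeric(cuboid_field(m, p)),
               cuboid_field_numeric(m, p, 128), tolerance = 5e-3)
  # 100 random points at least 5 mm from any face, < 0.5% max relative error
  pts <- points_outside(100, 0.0127 / 2, 0.005)
  Ba <- cuboid_field(m, pts)
  Bn <- t(vapply(seq_len(100),
                 function(i) cuboid_field_numeric(m, pts[i, ], 96),
                 numeric(3)))
  rel <- sqrt(rowSums((Ba - Bn)^2)) / sqrt(rowSums(Bn^2))
  expect_lt(max(rel), 5e-3)
  # interior point: full B including the magnetization term
  pin <- c(0.002, -0.001, 0.003)
  expect_equal(as.numeric(cuboid_field(m, pin)),
               cuboid_field_numeric(m, pin, 256), tolerance = 1e-3)
})

test_that("rotated magnet field equals rotated field of the unrotated magnet", {
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  m0 <- cuboid_magnet(c(0, 0, 0), 0.0127, c(1, 0, 0), 1.26, rotation = diag(3))
  m1 <- cuboid_magnet(c(0, 0, 0), 0.0127, as.numeric(R %*% c(1, 0, 0)), 1.26,
                      rotation = R)
  pts <- points_outside(20, 0.0127 / 2, 0.004, seed = 7)
  B0 <- cuboid_field(m0, pts %*% R)   # points rotated into the body frame
  B1 <- cuboid_field(m1, pts)
  expect_equal(B1, B0 %*% t(R), tolerance = 1e-12)
})

test_that("numeric oracle converges monotonically to the analytic field", {
  m <- main_cube(dir = c(0, 0, 1))
  pts <- points_outside(5, 0.0127 / 2, 0.004, seed = 3)
  errs <- vapply(c(8, 16, 32, 64), function(ns) {
    e <- vapply(seq_len(5), function(i) {
      max(abs(cuboid_field_numeric(m, pts[i, ], ns) -
                as.numeric(cuboid_field(m, pts[i, ]))))
    }, 0)
    max(e)
  }, 0)
  expect_true(all(diff(errs) < 0))
  m0 <- cuboid_magnet(c(0, 0, 0), 0.0127, c(0, 0, 1), 1e-12)
  expect_lt(max(abs(cuboid_field_numeric(m0, c(0.05, 0, 0), 8))), 1e-12)
})

test_that("field is numerically divergence-free away from sources", {
  m <- main_cube(dir = c(1, 0, 0))
  pts <- points_outside(20, 0.0127 / 2, 0.006, seed = 11)
  h <- 1e-6
  for (i in seq_len(10)) {
    p <- pts[i, ]
    div <- 0
    for (ax in 1:3) {
      dp <- rep(0, 3); dp[ax] <- h
      div <- div + (cuboid_field(m, p + dp)[ax] - cuboid_field(m, p - dp)[ax]) / (2 * h)
    }
    Bmag <- sqrt(sum(cuboid_field(m, p)^2))
    # dimensionless: |div B| * length-scale / |B|, length-scale 10 mm
    expect_lt(abs(div) * 0.01 / Bmag, 1e-4)
  }
})

test_that("far-field dipole error decreases monotonically with distance", {
  edge <- 0.0127
  m <- main_cube(dir = c(0, 0, 1))
  mom <- c(0, 0, 1.26 / mu0 * edge^3)
  dists <- edge * c(10, 15, 22, 33, 50)
  dirn <- c(0.3, -0.5, 0.81); dirn <- dirn / sqrt(sum(dirn^2))
  rel <- vapply(dists, function(r) {
    p <- r * dirn
    Ba <- as.numeric(cuboid_field(m, p))
    Bd <- as.numeric(dipole_field(mom, c(0, 0, 0), p))
    sqrt(sum((Ba - Bd)^2) / sum(Bd^2))
  }, 0)
  expect_true(all(diff(rel) < 0))
})

test_that("loop field reproduces closed forms and the Biot-Savart oracle", {
  R <- 0.0175
  cl <- loop_coil(c(0, 0, 0), c(0, 0, 1), R, turns = 1L)
  # center of a single loop
  expect_equal(loop_field(cl, c(0, 0, 0))[3], mu0 / (2 * R), tolerance = 1e-12)
  # on-axis formula
  z <- 0.03
  expect_equal(loop_field(cl, c(0, 0, z))[3],
               mu0 * R^2 / (2 * (R^2 + z^2)^1.5), tolerance = 1e-12)
  # turns scale linearly
  cl15 <- loop_coil(c(0, 0, 0), c(0, 0, 1), R, turns = 15L)
  expect_equal(loop_field(cl15, c(0, 0, z)), 15 * loop_field(cl, c(0, 0, z)),
               tolerance = 1e-14)
  # off-axis points vs polygonal Biot-Savart, < 0.5%
  set.seed(5)
  pts <- cbind(runif(12, -0.04, 0.04), runif(12, -0.04, 0.04),
               runif(12, 0.01, 0.05))
  Ba <- loop_field(cl15, pts, current = 0.8)
  Bn <- loop_field_numeric(cl15, pts, current = 0.8, n_seg = 2000)
  expect_lt(max(sqrt(rowSums((Ba - Bn)^2)) / sqrt(rowSums(Bn^2))), 5e-3)
  # tilted coil agrees with the oracle too
  ct <- loop_coil(c(0.01, -0.02, 0.015), c(1, 1, 1) / sqrt(3), R, 3L)
  pt <- matrix(c(0.05, 0.01, -0.02), 1)
  expect_equal(loop_field(ct, pt), loop_field_numeric(ct, pt, n_seg = 4000),
               tolerance = 1e-5)
  expect_error(loop_field(cl, c(R, 0, 0)), "filament")
})

test_that("superposition is linear, order-free, and zero for no sources", {
  pts <- points_outside(10, 0.0127 / 2, 0.004, seed = 9)
  expect_equal(superpose(list(), pts), matrix(0, 10, 3))
  m1 <- main_cube(c(0.03, 0, 0), c(1, 0, 0))
  m2 <- main_cube(c(-0.03, 0.01, 0), c(0, 1, 0))
  cl <- loop_coil(c(0, 0.05, 0), c(0, 1, 0), 0.0175, 15L)
  B12 <- superpose(list(m1, m2, cl), pts)
  Bsum <- cuboid_field(m1, pts) + cuboid_field(m2, pts) + loop_field(cl, pts)
  expect_equal(B12, Bsum, tolerance = 1e-12)
  # opposite magnetization at the same center cancels
  ma <- cuboid_magnet(c(0, 0, 0), 0.0127, c(1, 0, 0), 1.26, rotation = diag(3))
  mb <- cuboid_magnet(c(0, 0, 0), 0.0127, c(-1, 0, 0), 1.26, rotation = diag(3))
  expect_lt(max(abs(superpose(list(ma, mb), pts))), 1e-18)
})

test_that("batched cuboid evaluation equals per-magnet evaluation", {
  set.seed(13)
  mags <- lapply(seq_len(25), function(i) {
    phi <- runif(1, 0, 2 * pi)
    cuboid_magnet(c(0.15 * cos(phi), 0.15 * sin(phi), runif(1, -0.1, 0.1)),
                  0.0127, c(cos(2 * phi), sin(2 * phi), 0), 1.26)
  })
  pts <- matrix(runif(30, -0.04, 0.04), 10, 3)
  Bb <- cuboid_field(mags, pts)
  Bs <- Reduce(`+`, lapply(mags, cuboid_field, points = pts))
  expect_identical(Bb, Bs)
})

test_that("proton Larmor frequency is gammabar times field", {
  expect_equal(larmor_frequency(1), 42.577478518e6)
  expect_equal(larmor_frequency(0.043) / 1e6, 1.8308, tolerance = 1e-4)
})
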