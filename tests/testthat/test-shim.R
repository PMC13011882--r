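# passive shim placement and active shim current solving

dsv_sel <- function(map, dsv = 0.1) {
  pts <- grid_points(map)
  pts[rowSums(pts^2) <= (dsv / 2)^2 + 1e-12, , drop = FALSE]
}

test_that("shim field: empty mask is zero, one magnet equals cuboid_field", {
  con <- passive_shim_constraints()
  z <- rep(con$holder_center_z, con$rings_per_holder)
  empty <- passive_shim_solution(z, rep(0, 22), matrix(0L, 22, 25), con)
  pts <- matrix(c(0.01, 0.02, -0.01, 0, 0, 0.03), 2, 3, byrow = TRUE)
  expect_identical(shim_field(empty, pts), matrix(0, 2, 3))
  one <- passive_shim_solution(z, rep(0, 22),
                               {m <- matrix(0L, 22, 25); m[3, 7] <- 1L; m},
                               con)
  mags <- shim_magnets(one)
  expect_length(mags, 1L)
  expect_equal(shim_field(one, pts), cuboid_field(mags[[1]], pts),
               tolerance = 1e-15)
  expect_equal(mags[[1]]$edge, 0.003)
})

test_that("fully populated symmetric rings give transverse mirror symmetry", {
  con <- passive_shim_constraints(holder_z = c(0.126, 0.226))  # symmetric about center
  z <- rep(con$holder_center_z, con$rings_per_holder)
  full <- passive_shim_solution(z, rep(0, con$n_rings),
                                matrix(1L, con$n_rings, con$magnets_per_ring),
                                con)
  pts <- cbind(runif(20, -0.03, 0.03), runif(20, -0.03, 0.03),
               runif(20, -0.04, 0.04))
  refl <- pts; refl[, 3] <- -refl[, 3]
  B1 <- sqrt(rowSums(shim_field(full, pts)^2))
  B2 <- sqrt(rowSums(shim_field(full, refl)^2))
  expect_equal(B1, B2, tolerance = 1e-9)
})

test_that("solutions outside holder extents are rejected", {
  con <- passive_shim_constraints()
  z <- rep(con$holder_center_z, con$rings_per_holder)
  z[1] <- 0   # isocenter: not on a holder
  expect_error(passive_shim_solution(z, rep(0, 22), matrix(0L, 22, 25), con),
               "holder")
})

test_that("passive shim never worsens the map and needs no work on a uniform one", {
  fm <- uniform_map(n = 7L)
  fit <- optimize_passive_shim(fm, passive_shim_constraints(),
                               ga_params(population = 12L, generations = 6L,
                                         seed = 3L))
  expect_lte(fit$ppm_after, fit$ppm_before)
  expect_equal(fit$ppm_after, fit$ppm_before, tolerance = 1e-9)
  expect_equal(fit$improvement_pct, 0, tolerance = 1e-7)
})

test_that("GA matches exhaustive enumeration on a tiny mask-only instance", {
  con <- passive_shim_constraints(n_rings = 2L, magnets_per_ring = 3L,
                                  holder_span = 0.02)
  sm <- synthetic_inhomogeneity_map(ppm_target = 3000,
                                    grid = grid_spec(0.11, 7L), seed = 4L)
  pts_all <- grid_points(sm)
  sel <- rowSums(pts_all^2) <= 0.05^2 + 1e-12
  pts <- pts_all[sel, , drop = FALSE]
  Bmap <- sm$B[sel, , drop = FALSE]
  zfix <- con$holder_center_z[rep(1:2, con$rings_per_holder)]
  # brute force over all 2^6 masks at fixed z / zero rotation
  best <- Inf
  for (bits in 0:63) {
    mask <- matrix(as.integer(intToBits(bits))[1:6], 2, 3)
    sol <- passive_shim_solution(zfix, c(0, 0), mask, con)
    v <- homogeneity_objective(Bmap + shim_field(sol, pts))
    best <- min(best, v)
  }
  # GA restricted to the same search space: pin z and rotation via bounds
  nr <- con$n_rings
  ga <- ga_params(population = 24L, generations = 40L, seed = 9L,
                  bit_mutation_rate = 0.2)
  obj <- function(x, b) {
    sol <- passive_shim_solution(zfix, c(0, 0), matrix(b, nr, 3), con)
    homogeneity_objective(Bmap + shim_field(sol, pts))
  }
  res <- ga_minimize(obj, numeric(0), numeric(0), n_bits = 6L, params = ga)
  expect_equal(res$value, best, tolerance = 1e-9)
})

test_that("passive shim improves a low-order 3000 ppm map by a quarter or more", {
  sm <- synthetic_inhomogeneity_map(b0 = 0.043, ppm_target = 3000, seed = 7L)
  fit <- optimize_passive_shim(sm, passive_shim_constraints(),
                               ga_params(population = 40L, generations = 80L,
                                         patience = 40L, seed = 7L))
  expect_gte(fit$improvement_pct, 25)
  expect_true(all(diff(fit$trace) <= 1e-9))
})

test_that("active shim is linear in the currents", {
  arr <- active_shim_array(n_axial = 2L, n_azimuthal = 3L, axial_span = 0.1)
  pts <- cbind(runif(10, -0.03, 0.03), runif(10, -0.03, 0.03),
               runif(10, -0.03, 0.03))
  c1 <- runif(6, -0.5, 0.5); c2 <- runif(6, -0.5, 0.5)
  f <- function(cur) superpose(arr$coils, pts, currents = cur)
  expect_equal(f(c1 + c2), f(c1) + f(c2), tolerance = 1e-12)
})

test_that("active shim recovers a consistent perturbation and matches the
           pseudoinverse oracle", {
  arr <- active_shim_array()
  g <- grid_spec(0.11, 9L)
  pts <- grid_points(g)
  true_c <- rep(0, 30); true_c[c(3, 11, 20)] <- c(0.2, -0.35, 0.15)
  Bp <- matrix(0, nrow(pts), 3)
  for (i in c(3, 11, 20))
    Bp <- Bp + true_c[i] * loop_field(arr$coils[[i]], pts)
  B <- cbind(0.043, 0, 0)[rep(1, nrow(pts)), ] + Bp
  fm <- field_map(g$origin, g$spacing, g$dim, B)
  fit <- solve_active_shim(fm, arr, lambda = 1e-18)
  # consistent system: residual and shimmed ppm collapse to ~0
  expect_lt(fit$residual_rms, 1e-10)
  expect_lt(fit$ppm_after, 1e-2)
  expect_lte(fit$ppm_after, fit$ppm_before)
  expect_true(all(abs(fit$currents) <= arr$current_limit + 1e-12))
  # ridge solution matches the dense pseudoinverse oracle at the same lambda
  lam <- 1e-14
  fit2 <- solve_active_shim(fm, arr, lambda = lam)
  A <- fit2$basis
  A_c <- sweep(A, 2, colMeans(A))
  sel <- rowSums(pts^2) <= 0.05^2 + 1e-12
  d_c <- B[sel, 1] - mean(B[sel, 1])
  oracle <- -solve(crossprod(A_c) + lam * diag(30), crossprod(A_c, d_c))
  expect_equal(fit2$currents, as.numeric(oracle), tolerance = 1e-6)
})

test_that("active shim leaves a homogeneous map alone and flags singular bases", {
  fm <- uniform_map(n = 9L)
  fit <- solve_active_shim(fm, lambda = 1e-10)
  expect_identical(fit$currents, rep(0, 30))
  expect_error(solve_active_shim(fm, lambda = 0), "regulari")
})

test_that("random smooth perturbations are reduced by the active shim", {
  sm <- synthetic_inhomogeneity_map(ppm_target = 3000,
                                    grid = grid_spec(0.11, 9L), seed = 12L)
  fit <- solve_active_shim(sm)
  expect_lte(fit$ppm_after, fit$ppm_before)
  # the 1 A per-coil limit bounds how much of a ~130 uT peak-to-peak
  # perturbation the small coils can cancel
  expect_lt(fit$ppm_after, 0.75 * fit$ppm_before)
})
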