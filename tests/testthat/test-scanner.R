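# phantoms, spin-echo simulation, FFT reconstruction, timing, DICOM export

resampled_density <- function(ph, seq) {
  n <- seq$matrix
  halbachmri:::.resample3(ph$density, ph$voxel_size,
                          halbachmri:::.axis_coords(n[1], seq$fov[1] / n[1]),
                          halbachmri:::.axis_coords(n[2], seq$fov[2] / n[2]),
                          halbachmri:::.axis_coords(n[3], seq$fov[3] / n[3]))
}

test_that("mystery phantom: sphere volume and glyph carving", {
  # empty message: voxelized volume matches the sphere volume within 1%
  ph <- make_mystery_phantom(0.10, "", n = 96L)
  vol <- sum(ph$density) * prod(ph$voxel_size)
  expect_equal(vol, 4 / 3 * pi * 0.05^3, tolerance = 0.01)
  # message voxels carve zeros inside; all nonzero values are 1
  phm <- make_mystery_phantom(0.10, "HI", n = 96L)
  expect_true(all(phm$density %in% c(0, 1)))
  expect_lt(sum(phm$density), sum(ph$density))
  # a message too long for the resolution fails loudly
  expect_error(make_mystery_phantom(0.10, strrep("WWWW", 8), n = 32L),
               "too long")
  expect_error(make_mystery_phantom(0.10, "hé"), "glyph")
})

test_that("syringe phantom is two disjoint cylinders", {
  ph <- make_syringe_phantom(n = 48L)
  expect_true(all(ph$density %in% c(0, 1)))   # would be 2 if overlapping
  mid <- ph$density[, , 24]
  # two connected components along x at the mid-slice: density profile along
  # x has two separated runs
  prof <- rowSums(mid) > 0
  runs <- rle(prof)$values
  expect_identical(sum(runs), 2L)
})

test_that("noiseless undistorted recon inverts the simulation (NRMSE < 2%)", {
  ph <- make_syringe_phantom(n = 32L)
  sq <- sequence_params(matrix = c(32L, 32L, 32L), fov = 0.11)
  ks <- simulate_spin_echo(ph, sq)
  rec <- reconstruct_fft(ks)
  expect_lt(image_nrmse(rec, resampled_density(ph, sq)), 0.02)
})

test_that("k-space center delta reconstructs to a constant image", {
  sq <- sequence_params(matrix = c(8L, 8L, 4L), fov = 0.1)
  ord <- as.matrix(expand.grid(phase = 1:8, slice = 1:4))
  samples <- matrix(0i, 8, 32)
  dc_line <- which(ord[, 1] == 5L & ord[, 2] == 3L)  # DC at n%/%2+1
  samples[5, dc_line] <- 1 + 0i
  k <- structure(list(samples = samples, order = ord,
                      matrix = sq$matrix, seq = sq, provenance = list()),
                 class = "kspace")
  img <- reconstruct_fft(k)$data
  expect_lt(diff(range(img)), 1e-12 * max(img))
})

test_that("acquisition order is metadata: permuted acquisition reconstructs
           identically, bad orderings error", {
  ph <- make_syringe_phantom(n = 16L)
  sq <- sequence_params(matrix = c(16L, 16L, 4L), fov = 0.11)
  ord <- as.matrix(expand.grid(phase = 1:16, slice = 1:4))
  set.seed(8)
  perm <- sample(nrow(ord))
  k_seq <- simulate_spin_echo(ph, sq)
  k_per <- simulate_spin_echo(ph, sq, ordering = ord[perm, ])
  r1 <- reconstruct_fft(k_seq)$data
  r2 <- reconstruct_fft(k_per)$data
  expect_equal(r2, r1, tolerance = 1e-12)
  bad <- ord; bad[2, ] <- bad[1, ]
  expect_error(simulate_spin_echo(ph, sq, ordering = bad), "exactly once")
  expect_error(reconstruct_fft(k_seq, ordering = ord[-1, ]), "exactly once")
})

test_that("uniform off-resonance shifts the image along readout by
           df / bandwidth-per-pixel pixels", {
  n <- 32L
  ph <- make_syringe_phantom(n = n)
  sq <- sequence_params(matrix = c(n, n, 4L), fov = 0.11,
                        bandwidth_per_pixel = 200)
  r0 <- reconstruct_fft(simulate_spin_echo(ph, sq))$data
  for (shift_px in c(2L, 5L)) {
    db <- shift_px * sq$bandwidth_per_pixel / halbachmri:::GAMMABAR_PROTON
    r1 <- reconstruct_fft(simulate_spin_echo(ph, sq, delta_b0 = db))$data
    # displacement is -df/bwpp along readout with this gradient polarity
    idx <- c((shift_px + 1L):n, 1:shift_px)
    expect_lt(max(abs(r1 - r0[idx, , ])), 1e-10 * max(r0))
  }
})

test_that("distortion displacement scales linearly with dB0 amplitude", {
  n <- 24L
  # smooth Gaussian blob: no Gibbs ringing, so the magnitude-image center of
  # mass tracks the true sub-pixel displacement
  vox <- 0.11 / n
  co <- halbachmri:::.axis_coords(n, vox)
  r2 <- outer(outer(co^2, co^2, `+`), co^2 * 0, `+`)
  blob <- array(exp(-r2 / (2 * 0.012^2)), c(n, n, 2L))
  ph <- phantom(blob[, , 1:2], c(vox, vox, 0.11 / 2))
  sq <- sequence_params(matrix = c(n, n, 2L), fov = 0.11,
                        bandwidth_per_pixel = 200)
  # center-of-mass displacement along readout of the reconstructed image
  com <- function(img) {
    w <- apply(img, 1, sum)
    sum(seq_len(n) * w) / sum(w)
  }
  base <- com(reconstruct_fft(simulate_spin_echo(ph, sq))$data)
  amps <- c(1, 2, 3) * 1e-6
  disp <- vapply(amps, function(a) {
    db <- array(a, c(n, n, 2L))
    com(reconstruct_fft(simulate_spin_echo(ph, sq, delta_b0 = db))$data) - base
  }, 0)
  fitl <- lm(disp ~ amps)
  # slope in pixels per tesla: -gammabar / bwpp
  expect_equal(unname(coef(fitl)[2]),
               -halbachmri:::GAMMABAR_PROTON / sq$bandwidth_per_pixel,
               tolerance = 0.05)
  expect_lt(abs(coef(fitl)[1]), 0.05)
  # and halving the readout bandwidth doubles the displacement
  sq2 <- sequence_params(matrix = c(n, n, 2L), fov = 0.11,
                         bandwidth_per_pixel = 100)
  b2 <- com(reconstruct_fft(simulate_spin_echo(ph, sq2))$data)
  d2 <- com(reconstruct_fft(simulate_spin_echo(
    ph, sq2, delta_b0 = array(2e-6, c(n, n, 2L))))$data) - b2
  expect_equal(d2, 2 * disp[2], tolerance = 0.06)
})

test_that("k-space energy equals image energy (unitary transform)", {
  ph <- make_syringe_phantom(n = 16L)
  sq <- sequence_params(matrix = c(16L, 16L, 8L), fov = 0.11)
  ks <- simulate_spin_echo(ph, sq)
  rho <- resampled_density(ph, sq)
  expect_equal(sum(Mod(ks$samples)^2), sum(rho^2), tolerance = 1e-10)
})

test_that("2d multislice encoding reconstructs each slice independently", {
  ph <- make_syringe_phantom(n = 16L)
  sq <- sequence_params(matrix = c(16L, 16L, 4L), fov = 0.11,
                        encoding = "2d")
  rec <- reconstruct_fft(simulate_spin_echo(ph, sq))
  expect_lt(image_nrmse(rec, resampled_density(ph, sq)), 0.02)
})

test_that("noise is seed-reproducible and absent when sd = 0", {
  ph <- make_syringe_phantom(n = 8L)
  sq <- sequence_params(matrix = c(8L, 8L, 2L), fov = 0.11)
  k1 <- simulate_spin_echo(ph, sq, noise_sd = 0.1, seed = 4L)
  k2 <- simulate_spin_echo(ph, sq, noise_sd = 0.1, seed = 4L)
  expect_identical(k1$samples, k2$samples)
  k3 <- simulate_spin_echo(ph, sq, noise_sd = 0.1, seed = 5L)
  expect_false(identical(k1$samples, k3$samples))
})

test_that("acquisition time follows the shot count", {
  expect_equal(acquisition_time(sequence_params(TR = 1, matrix = c(8, 1, 1))),
               1)
  s1 <- sequence_params(TR = 0.5, matrix = c(384L, 384L, 16L))
  expect_equal(acquisition_time(s1), 0.5 * 384 * 16)
  s2 <- sequence_params(TR = 0.5, matrix = c(384L, 768L, 16L))
  expect_equal(acquisition_time(s2), 2 * acquisition_time(s1))
  # dummy shots add TR each
  s3 <- sequence_params(TR = 0.5, matrix = c(64L, 8L, 2L), dummy_shots = 4L)
  expect_equal(acquisition_time(s3), 0.5 * (16 + 4))
  # 2d multislice: all slices within one TR
  s4 <- sequence_params(TR = 0.5, matrix = c(64L, 8L, 4L), encoding = "2d")
  expect_equal(acquisition_time(s4), 0.5 * 8)
  expect_error(sequence_params(TE = 0.6, TR = 0.5), "TE")
})

test_that("mystery message is legible in the recon and survives distortion", {
  msg <- "Z1"
  ph <- make_mystery_phantom(0.10, msg, n = 48L)
  sq <- sequence_params(matrix = c(48L, 48L, 16L), fov = 0.11)
  rec0 <- reconstruct_fft(simulate_spin_echo(ph, sq))$data
  rho <- resampled_density(ph, sq)
  # glyph voxels: carved (zero) but inside the sphere
  sphere <- resampled_density(make_mystery_phantom(0.10, "", n = 48L), sq)
  glyph <- sphere > 0.9 & rho < 0.1
  bulk <- rho > 0.9
  expect_gt(sum(glyph), 20)
  contrast0 <- mean(rec0[bulk]) - mean(rec0[glyph])
  expect_gt(contrast0, 5 * sd(rec0[bulk]))
  # under a 3000 ppm-scale field map the message degrades but remains
  sm <- synthetic_inhomogeneity_map(ppm_target = 3000, seed = 2L)
  rec1 <- reconstruct_fft(simulate_spin_echo(ph, sq, delta_b0 = sm))$data
  contrast1 <- mean(rec1[bulk]) - mean(rec1[glyph])
  expect_gt(contrast1, 0.3 * contrast0)
})

test_that("DICOM series round-trips pixels and geometry", {
  ph <- make_syringe_phantom(n = 16L)
  sq <- sequence_params(matrix = c(16L, 12L, 5L), fov = c(0.11, 0.1, 0.05))
  img <- reconstruct_fft(simulate_spin_echo(ph, sq))
  dd <- file.path(tempdir(), "dcm_test")
  files <- export_dicom(img, dd)
  expect_length(files, 5L)                    # one file per slice
  s3 <- read_dicom_slice(files[3])
  expect_identical(s3$rows, 12L)              # phase
  expect_identical(s3$cols, 16L)              # readout
  expect_equal(s3$pixel_spacing_mm,
               c(img$voxel_size[2], img$voxel_size[1]) * 1e3,
               tolerance = 1e-6)
  expect_identical(s3$instance_number, 3L)
  # pixel values reproduce the quantized image exactly
  expect_identical(t(s3$pixel),
                   matrix(as.integer(round(img$data[, , 3] /
                                             s3$rescale_slope)), 16, 12))
  # slices share a series UID, slice locations step by the voxel size
  s1 <- read_dicom_slice(files[1])
  expect_identical(s1$series_uid, s3$series_uid)
  expect_false(identical(s1$sop_instance_uid, s3$sop_instance_uid))
  expect_equal(s3$slice_location_mm - s1$slice_location_mm,
               2 * img$voxel_size[3] * 1e3, tolerance = 1e-6)
  expect_error(export_dicom(img, file.path("/proc/definitely/not/writable")))
})
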