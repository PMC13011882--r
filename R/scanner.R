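## Virtual scanner: spin-echo k-space simulation under B0 inhomogeneity and
## FFT reconstruction.
##
## Signal model: after the refocusing pulse the static-field dephasing is
## refocused at TE, so off-resonance phase accrues only with the time offset
## from the echo center during readout,
##     s(k) = sum_r rho(r) exp(-i 2 pi k.r) exp(i 2 pi gammabar dB0(r) t(k)),
## with t(k) = k_read / (N_read * bandwidth_per_pixel).  This reproduces the
## geometric distortion along the readout axis (shift = dF/bandwidth_per_pixel
## pixels) without a full Bloch solver.  T2 decay is an optional per-voxel
## exponential at TE.

#' Spin-echo sequence parameters
#'
#' @param TE echo time, seconds.
#' @param TR repetition time, seconds (> TE).
#' @param matrix integer 3-vector: readout x phase x slice encodes.
#' @param fov field of view, meters (scalar or 3-vector).
#' @param bandwidth_per_pixel readout bandwidth, Hz/pixel.  Geometric
#'   distortion scales inversely with it.
#' @param encoding `"3d"` (slab with slice encoding, default) or `"2d"`
#'   (multislice: all slices acquired within each TR).
#' @param dummy_shots initial excitations without acquisition.
#' @return object of class `sequence_params`.
#' @export
sequence_params <- function(TE = 0.020, TR = 0.500,
                            matrix = c(64L, 64L, 8L), fov = 0.11,
                            bandwidth_per_pixel = 200,
                            encoding = c("3d", "2d"), dummy_shots = 0L) {
  encoding <- match.arg(encoding)
  matrix <- as.integer(matrix)
  if (length(fov) == 1L) fov <- rep(fov, 3L)
  stopifnot(TE > 0, TR > TE, length(matrix) == 3L, all(matrix >= 1L),
            all(fov > 0), bandwidth_per_pixel > 0, dummy_shots >= 0)
  structure(list(TE = TE, TR = TR, matrix = matrix, fov = as.numeric(fov),
                 bandwidth_per_pixel = bandwidth_per_pixel,
                 encoding = encoding, dummy_shots = as.integer(dummy_shots)),
            class = "sequence_params")
}

#' Total acquisition time of a spin-echo protocol
#'
#' One phase-encode line per TR: for 3D slab encoding
#' `TA = TR * (phase * slice + dummy_shots)`; for 2D multislice all slices are
#' acquired within each TR, so `TA = TR * (phase + dummy_shots)`.
#'
#' @param seq a [sequence_params()].
#' @return acquisition time in seconds.
#' @examples
#' # 384 x 16 encodes at TR 500 ms: 3072 s, i.e. 51 min 12 s
#' acquisition_time(sequence_params(matrix = c(384, 384, 16)))
#' @export
acquisition_time <- function(seq) {
  stopifnot(inherits(seq, "sequence_params"))
  shots <- if (seq$encoding == "3d") seq$matrix[2] * seq$matrix[3]
           else seq$matrix[2]
  seq$TR * (shots + seq$dummy_shots)
}

## centered unitary DFT helpers ---------------------------------------------

.shift_idx <- function(n, inverse = FALSE) {
  if (n == 1L) return(1L)
  h <- if (inverse) ceiling(n / 2) else floor(n / 2)
  c((h + 1L):n, seq_len(h))
}

.fftshift <- function(a) {
  d <- dim(a)
  a[.shift_idx(d[1]), .shift_idx(d[2]), .shift_idx(d[3]), drop = FALSE]
}

.ifftshift <- function(a) {
  d <- dim(a)
  a[.shift_idx(d[1], TRUE), .shift_idx(d[2], TRUE), .shift_idx(d[3], TRUE),
    drop = FALSE]
}

# centered unitary 3D DFT: image with center voxel at index n%/%2+1 ->
# k-space with DC at index n%/%2+1
.cdft3 <- function(a) {
  .fftshift(array(fft(.ifftshift(a)), dim = dim(a))) / sqrt(prod(dim(a)))
}

# trilinear resampling of a 3D array from centered grid (voxel vx) to target
# coordinates given per axis; outside the source grid -> 0
.resample3 <- function(arr, src_vox, xt, yt, zt) {
  d <- dim(arr)
  locate <- function(co, n, vox) {
    u <- co / vox + (n + 1) / 2    # fractional source index
    i0 <- floor(u)
    list(i0 = i0, w = u - i0)
  }
  lx <- locate(xt, d[1], src_vox[1])
  ly <- locate(yt, d[2], src_vox[2])
  lz <- locate(zt, d[3], src_vox[3])
  out <- array(0, c(length(xt), length(yt), length(zt)))
  padded <- array(0, d + 2L)
  padded[1L + seq_len(d[1]), 1L + seq_len(d[2]), 1L + seq_len(d[3])] <- arr
  clamp <- function(i, n) pmin(pmax(i + 1L, 0L), n + 1L) + 1L  # into padded
  for (a in 0:1) for (b in 0:1) for (cc in 0:1) {
    wx <- if (a) lx$w else 1 - lx$w
    wy <- if (b) ly$w else 1 - ly$w
    wz <- if (cc) lz$w else 1 - lz$w
    sub <- padded[clamp(lx$i0 + a - 1L, d[1]),
                  clamp(ly$i0 + b - 1L, d[2]),
                  clamp(lz$i0 + cc - 1L, d[3]), drop = FALSE]
    out <- out + sub * (wx %o% wy %o% wz)
  }
  out
}

#' Simulate a spin-echo acquisition
#'
#' Samples the k-space of the phantom under the off-resonance signal model
#' described above.  With `delta_b0 = NULL` (or zero) and no noise the
#' k-space is exactly the centered unitary DFT of the phantom resampled to
#' the sequence grid, so reconstruction inverts it.
#'
#' @param phantom a [phantom()].
#' @param seq a [sequence_params()].
#' @param delta_b0 B0 inhomogeneity: `NULL` (none), a scalar (uniform
#'   off-resonance, tesla), a 3D array of tesla offsets on the sequence grid,
#'   or a [field_map()] whose `|B|` deviation from its DSV mean is resampled
#'   onto the sequence grid.
#' @param noise_sd complex-noise standard deviation per sample (same units as
#'   the density sum).
#' @param seed integer seed for the noise stream.
#' @param ordering optional acquisition order, an `n_lines x 2` matrix of
#'   (phase, slice) indices; default sequential raster.
#' @return object of class `kspace`: `samples` (complex, readout x lines, in
#'   acquisition order), `order`, `matrix`, `seq`, `provenance`.
#' @export
simulate_spin_echo <- function(phantom, seq, delta_b0 = NULL, noise_sd = 0,
                               seed = NULL, ordering = NULL) {
  stopifnot(inherits(phantom, "phantom"), inherits(seq, "sequence_params"))
  nx <- seq$matrix[1]; ny <- seq$matrix[2]; nz <- seq$matrix[3]
  prov <- list()
  # resample the phantom onto the sequence grid
  xt <- .axis_coords(nx, seq$fov[1] / nx)
  yt <- .axis_coords(ny, seq$fov[2] / ny)
  zt <- .axis_coords(nz, seq$fov[3] / nz)
  ext <- dim(phantom$density) * phantom$voxel_size
  if (any(ext > seq$fov + 1e-12)) {
    supp <- which(phantom$density > 0, arr.ind = TRUE)
    if (nrow(supp)) {
      span <- (apply(supp, 2, function(i) diff(range(i)) + 1)) *
        phantom$voxel_size
      if (any(span > seq$fov + 1e-12))
        prov$aliasing_warning <-
          "phantom extent exceeds FOV; object will alias"
    }
  }
  rho <- .resample3(phantom$density, phantom$voxel_size, xt, yt, zt)
  if (!is.null(phantom$T2))
    rho <- rho * exp(-seq$TE /
                       .resample3(phantom$T2, phantom$voxel_size, xt, yt, zt))
  # off-resonance map (tesla) on the sequence grid
  db <- NULL
  if (inherits(delta_b0, "field_map")) {
    mag <- sqrt(rowSums(delta_b0$B^2))
    marr <- array(mag, delta_b0$dim)
    ctr <- delta_b0$origin + (delta_b0$dim - 1) / 2 * delta_b0$spacing
    db <- .resample3(marr, delta_b0$spacing, xt - ctr[1] + 0,
                     yt - ctr[2] + 0, zt - ctr[3] + 0)
    ref <- mean(db[rho > 0])
    if (!is.finite(ref)) ref <- mean(db)
    db <- db - ref
    prov$delta_b0 <- "field map"
  } else if (is.numeric(delta_b0) && length(delta_b0) == 1L) {
    if (delta_b0 != 0) {
      db <- array(delta_b0, c(nx, ny, nz))
      prov$delta_b0 <- sprintf("uniform %.3g T", delta_b0)
    }
  } else if (is.array(delta_b0)) {
    stopifnot(all(dim(delta_b0) == c(nx, ny, nz)))
    db <- delta_b0
    prov$delta_b0 <- "array"
  } else if (!is.null(delta_b0)) stop("unsupported delta_b0")

  if (is.null(ordering)) {
    ordering <- as.matrix(expand.grid(phase = seq_len(ny),
                                      slice = seq_len(nz)))
  }
  .check_ordering(ordering, ny, nz)

  K <- array(0i, c(nx, ny, nz))
  dt <- 1 / (nx * seq$bandwidth_per_pixel)
  kx <- seq_len(nx) - (nx %/% 2 + 1L)   # centered readout index
  if (is.null(db)) {
    if (seq$encoding == "3d") {
      K <- .cdft3(rho)
    } else {
      for (s in seq_len(nz))
        K[, , s] <- .cdft3(rho[, , s, drop = FALSE])
    }
  } else {
    phase_rate <- 2 * pi * GAMMABAR_PROTON * db   # rad/s per voxel
    for (n in seq_len(nx)) {
      w <- rho * exp(1i * phase_rate * (kx[n] * dt))
      if (seq$encoding == "3d") {
        Kn <- .cdft3(w)
        K[n, , ] <- Kn[n, , ]
      } else {
        for (s in seq_len(nz)) {
          Kn <- .cdft3(w[, , s, drop = FALSE])
          K[n, , s] <- Kn[n, , 1]
        }
      }
    }
  }
  # collect lines in acquisition order
  samples <- matrix(0i, nx, nrow(ordering))
  for (j in seq_len(nrow(ordering)))
    samples[, j] <- K[, ordering[j, 1], ordering[j, 2]]
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    samples <- samples +
      complex(real = rnorm(length(samples), sd = noise_sd),
              imaginary = rnorm(length(samples), sd = noise_sd))
  }
  prov$noise_sd <- noise_sd
  prov$seed <- seed
  structure(list(samples = samples, order = ordering, matrix = seq$matrix,
                 seq = seq, provenance = prov),
            class = "kspace")
}

.check_ordering <- function(ordering, ny, nz) {
  ordering <- as.matrix(ordering)
  if (ncol(ordering) != 2L) stop("ordering must have two columns (phase, slice)")
  key <- (ordering[, 1] - 1L) * nz + ordering[, 2]
  if (nrow(ordering) != ny * nz || anyDuplicated(key) ||
      any(ordering[, 1] < 1L | ordering[, 1] > ny |
          ordering[, 2] < 1L | ordering[, 2] > nz))
    stop("acquisition ordering must cover every (phase, slice) line exactly once")
  invisible(TRUE)
}

#' @export
print.kspace <- function(x, ...) {
  cat(sprintf("<k-space> %d x %d x %d (%s), %d lines\n", x$matrix[1],
              x$matrix[2], x$matrix[3], x$seq$encoding, ncol(x$samples)))
  invisible(x)
}

#' Reconstructed image volume
#'
#' @param data non-negative 3D magnitude array.
#' @param voxel_size 3-vector, meters.
#' @param provenance named list describing sequence and reconstruction.
#' @return object of class `image_volume`.
#' @export
image_volume <- function(data, voxel_size, provenance = list()) {
  stopifnot(length(dim(data)) == 3L, all(data >= 0), all(is.finite(data)))
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  structure(list(data = data, voxel_size = as.numeric(voxel_size),
                 provenance = provenance), class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<image volume> %d x %d x %d, voxel %.2f x %.2f x %.2f mm\n",
              d[1], d[2], d[3], x$voxel_size[1] * 1e3, x$voxel_size[2] * 1e3,
              x$voxel_size[3] * 1e3))
  invisible(x)
}

#' FFT reconstruction of acquired k-space
#'
#' Reorders the acquired lines onto the Cartesian grid and applies the
#' inverse centered unitary FFT (3D, or 2D per slice for multislice data),
#' returning the magnitude image.  The reconstruction is linear in the
#' k-space data and invariant to the acquisition order.  An ordering that
#' omits or duplicates lines raises an error.
#'
#' @param k a `kspace` object.
#' @param ordering optional override of the ordering stored in `k`.
#' @return an [image_volume()].
#' @export
reconstruct_fft <- function(k, ordering = NULL) {
  stopifnot(inherits(k, "kspace"))
  ord <- if (is.null(ordering)) k$order else as.matrix(ordering)
  nx <- k$matrix[1]; ny <- k$matrix[2]; nz <- k$matrix[3]
  .check_ordering(ord, ny, nz)
  K <- array(0i, c(nx, ny, nz))
  for (j in seq_len(nrow(ord)))
    K[, ord[j, 1], ord[j, 2]] <- k$samples[, j]
  if (k$seq$encoding == "3d") {
    img <- .cdft3_inv_unitary(K)
  } else {
    img <- array(0i, c(nx, ny, nz))
    for (s in seq_len(nz))
      img[, , s] <- .cdft3_inv_unitary(K[, , s, drop = FALSE])
  }
  image_volume(Mod(img), k$seq$fov / k$matrix,
               c(k$provenance, list(encoding = k$seq$encoding,
                                    recon = "centered unitary inverse FFT")))
}

# unitary inverse of .cdft3's forward transform
.cdft3_inv_unitary <- function(K) {
  n <- prod(dim(K))
  .fftshift(array(fft(.ifftshift(K), inverse = TRUE), dim = dim(K))) / sqrt(n)
}

#' Normalized RMS error between an image and a reference
#'
#' `sqrt(mean((a-b)^2)) / (max(b) - min(b))`, after scaling `a` by the
#' least-squares factor onto `b` (reconstruction is linear, absolute scale is
#' arbitrary).
#'
#' @param img an [image_volume()] or array.
#' @param ref reference array of the same shape.
#' @return scalar NRMSE.
#' @export
image_nrmse <- function(img, ref) {
  a <- if (inherits(img, "image_volume")) img$data else img
  stopifnot(all(dim(a) == dim(ref)))
  s <- sum(a * ref) / sum(a^2)
  sqrt(mean((s * a - ref)^2)) / (max(ref) - min(ref))
}
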