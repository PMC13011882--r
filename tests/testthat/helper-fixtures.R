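# shared fixtures built in code

mu0 <- 4e-7 * pi

main_cube <- function(center = c(0, 0, 0), dir = c(0, 0, 1), Br = 1.26)
  cuboid_magnet(center, 0.0127, dir, Br)

shim_cube <- function(center = c(0.0665, 0, 0), dir = c(1, 0, 0), Br = 1.26)
  cuboid_magnet(center, 0.003, dir, Br)

# uniform-field map on a cubic grid
uniform_map <- function(b0 = 0.043, n = 7L, extent = 0.11) {
  g <- grid_spec(extent, n)
  field_map(g$origin, g$spacing, g$dim,
            cbind(rep(b0, prod(g$dim)), 0, 0))
}

# random points at least `clear` away from a cube face of half-edge h
points_outside <- function(n, h, clear, lim = 0.06, seed = 1) {
  set.seed(seed)
  pts <- matrix(0, 0, 3)
  while (nrow(pts) < n) {
    p <- matrix(runif(3 * n, -lim, lim), ncol = 3)
    keep <- apply(abs(p), 1, max) > h + clear
    pts <- rbind(pts, p[keep, , drop = FALSE])
  }
  pts[seq_len(n), , drop = FALSE]
}
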