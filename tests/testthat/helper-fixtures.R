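# Fixtures built in code: analytic plane-wave chunks (independent of the
# package's phantom generator) and small hand-made vector fields.

# Pure cosine grating sampled on the anisotropic acquisition grid. theta/phi
# follow the package angle convention (elevation from XY, azimuth from +Y).
plane_wave_chunk <- function(theta, phi, period_um = 1.8,
                             voxel = c(2, 0.44, 0.44),
                             dims = c(8L, 36L, 36L), phase = 0) {
  u <- c(cos(theta * pi / 180) * sin(phi * pi / 180),
         cos(theta * pi / 180) * cos(phi * pi / 180),
         sin(theta * pi / 180))
  z <- (seq_len(dims[1]) - 1) * voxel[1]
  y <- (seq_len(dims[2]) - 1) * voxel[2]
  x <- (seq_len(dims[3]) - 1) * voxel[3]
  proj <- outer(outer(z * u[3], y * u[2], "+"), x * u[1], "+")
  array(0.5 + 0.5 * cos(2 * pi * (proj / period_um + phase)), dims)
}

angle_between_deg <- function(a, b) {
  acos(min(1, abs(sum(a * b)) / sqrt(sum(a^2) * sum(b^2)))) * 180 / pi
}

# Hand-built uniform vector field on an (nz, ny, nx) chunk grid, all vectors
# along +Y, all reliable; for disarray and outlier tests.
uniform_field <- function(gd = c(3L, 3L, 3L), chunk_um = 16) {
  grid <- tidyr::expand_grid(iz = seq_len(gd[1]), iy = seq_len(gd[2]),
                             ix = seq_len(gd[3]))
  tb <- dplyr::mutate(grid,
    z0 = 0L, y0 = 0L, x0 = 0L,
    zc_um = iz * chunk_um, yc_um = iy * chunk_um, xc_um = ix * chunk_um,
    tissue_fraction = 1, is_tissue = TRUE,
    vx = 0, vy = 1, vz = 0,
    frequency_um1 = 1 / 1.8, period_um = 1.8,
    sratio_raw = 0.5, sratio_norm = 0.5,
    is_reliable = TRUE, is_outlier = FALSE)
  myodisarray:::new_vector_field(tb, grid_dim = gd, chunk_um = chunk_um,
                                 voxel = c(2, 0.44, 0.44))
}

# Brute-force orientation oracle: scan a 1-degree (theta, phi) grid and keep
# the direction whose in-band ray through the smoothed *unfiltered* PSD
# carries the most energy. Independent of the argmax/centroid code path.
brute_force_orientation <- function(chunk, theta_range = c(-25, 25),
                                    phi_range = c(-89, 90),
                                    radii = seq(8, 10, by = 0.5)) {
  sp <- pad_spectrum(chunk)
  filt <- make_shell_filter(dim(sp)[1])
  ps <- smoothed_psds(sp, filt)
  ctr <- ps$center
  thetas <- seq(theta_range[1], theta_range[2], by = 1)
  phis <- seq(phi_range[1], phi_range[2], by = 1)
  grid <- as.matrix(expand.grid(theta = thetas, phi = phis))
  tr <- grid[, 1] * pi / 180
  pr <- grid[, 2] * pi / 180
  u <- cbind(cos(tr) * sin(pr), cos(tr) * cos(pr), sin(tr))  # (x, y, z)
  energy <- rep(0, nrow(grid))
  for (r in radii) {
    pts <- cbind(ctr[1] - 1 + r * u[, 3], ctr[2] - 1 + r * u[, 2],
                 ctr[3] - 1 + r * u[, 1])  # (z, y, x) in voxel units
    energy <- energy + myodisarray:::trilinear_sample(ps$sxx, c(1, 1, 1), pts)
  }
  best <- which.max(energy)
  c(cos(tr[best]) * sin(pr[best]), cos(tr[best]) * cos(pr[best]), sin(tr[best]))
}
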