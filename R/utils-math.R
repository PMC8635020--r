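# Shared numerical primitives: FFT shifts, separable Gaussian convolution,
# trilinear resampling and angle/vector conversions. Internal.

# Swap half-spaces so the zero-frequency bin sits at n %/% 2 + 1 per axis
# (even-length axes only, which is all this pipeline uses).
fftshift3 <- function(x) {
  d <- dim(x)
  idx <- lapply(d, function(n) c((n %/% 2 + 1L):n, seq_len(n %/% 2)))
  x[idx[[1]], idx[[2]], idx[[3]]]
}

gauss_kernel_1d <- function(sigma, radius = max(1L, ceiling(3 * sigma))) {
  if (sigma <= 0) return(1)
  k <- exp(-((-radius:radius)^2) / (2 * sigma^2))
  k / sum(k)
}

# 1D convolution along one axis of a 3D array, reflect padding at edges.
conv_axis3 <- function(x, k, axis) {
  if (length(k) == 1L) return(x)
  r <- (length(k) - 1L) %/% 2L
  d <- dim(x)
  n <- d[axis]
  out <- array(0, d)
  for (j in seq_along(k)) {
    off <- j - r - 1L
    idx <- seq_len(n) + off
    idx[idx < 1L] <- 2L - idx[idx < 1L]
    idx[idx > n] <- 2L * n - idx[idx > n]
    idx <- pmin(pmax(idx, 1L), n)  # axes shorter than the kernel
    out <- out + k[j] * switch(axis, x[idx, , , drop = FALSE],
                               x[, idx, , drop = FALSE],
                               x[, , idx, drop = FALSE])
  }
  out
}

# Separable Gaussian smoothing of a 3D array; sigma per (z, y, x) axis in
# voxels. sigma of 0 skips the axis.
gaussian_smooth_3d <- function(x, sigma, radius = NULL) {
  sigma <- rep_len(sigma, 3L)
  for (ax in 1:3) {
    if (sigma[ax] > 0) {
      k <- if (is.null(radius)) gauss_kernel_1d(sigma[ax]) else
        gauss_kernel_1d(sigma[ax], radius)
      x <- conv_axis3(x, k, ax)
    }
  }
  x
}

# Trilinear sampling of a (z,y,x) array at physical points.
# pts: n x 3 matrix of (z, y, x) coordinates in um; the centre of voxel
# [i,j,k] sits at ((i-1)*dz, (j-1)*dy, (k-1)*dx). Points outside the grid
# return `outside`.
trilinear_sample <- function(a, voxel, pts, outside = 0) {
  d <- dim(a)
  ci <- sweep(pts, 2, voxel, "/") + 1   # continuous 1-based index
  lo <- floor(ci)
  fr <- ci - lo
  inb <- ci[, 1] >= 1 & ci[, 1] <= d[1] &
    ci[, 2] >= 1 & ci[, 2] <= d[2] &
    ci[, 3] >= 1 & ci[, 3] <= d[3]
  # clamp so corner gathers are legal; out-of-bounds rows overwritten after
  z0 <- pmin(pmax(lo[, 1], 1), d[1]); z1 <- pmin(z0 + 1, d[1])
  y0 <- pmin(pmax(lo[, 2], 1), d[2]); y1 <- pmin(y0 + 1, d[2])
  x0 <- pmin(pmax(lo[, 3], 1), d[3]); x1 <- pmin(x0 + 1, d[3])
  fz <- pmin(pmax(fr[, 1], 0), 1)
  fy <- pmin(pmax(fr[, 2], 0), 1)
  fx <- pmin(pmax(fr[, 3], 0), 1)
  nz <- d[1]; nzy <- d[1] * d[2]
  g <- function(z, y, x) a[z + (y - 1) * nz + (x - 1) * nzy]
  val <-
    g(z0, y0, x0) * (1 - fz) * (1 - fy) * (1 - fx) +
    g(z1, y0, x0) * fz * (1 - fy) * (1 - fx) +
    g(z0, y1, x0) * (1 - fz) * fy * (1 - fx) +
    g(z0, y0, x1) * (1 - fz) * (1 - fy) * fx +
    g(z1, y1, x0) * fz * fy * (1 - fx) +
    g(z1, y0, x1) * fz * (1 - fy) * fx +
    g(z0, y1, x1) * (1 - fz) * fy * fx +
    g(z1, y1, x1) * fz * fy * fx
  val[!inb] <- outside
  val
}

#' Direction vector from azimuth and elevation
#'
#' Angle convention used throughout: `phi` is the azimuth in the XY imaging
#' plane measured from the +Y (traction) axis toward +X, `theta` the
#' elevation out of the XY plane toward +Z. Both in degrees.
#'
#' @param theta,phi angles in degrees.
#' @return unit vector `(vx, vy, vz)`.
#' @export
#' @examples
#' dir_from_angles(0, 0)   # +Y
#' dir_from_angles(90, 0)  # +Z
dir_from_angles <- function(theta, phi) {
  t <- theta * pi / 180
  p <- phi * pi / 180
  c(cos(t) * sin(p), cos(t) * cos(p), sin(t))
}

#' Azimuth and elevation from a direction vector
#'
#' Inverse of [dir_from_angles()]; the vector need not be unit length.
#'
#' @param v numeric length-3 `(vx, vy, vz)`.
#' @return named numeric `c(theta, phi)` in degrees.
#' @export
angles_from_dir <- function(v) {
  n <- sqrt(sum(v^2))
  c(theta = asin(max(-1, min(1, v[3] / n))) * 180 / pi,
    phi = atan2(v[1], v[2]) * 180 / pi)
}

# Rotation taking +Y to dir_from_angles(theta, phi): theta about X (toward
# +Z), then phi about Z (from +Y toward +X). Acts on (x, y, z) columns.
rotation_matrix <- function(theta, phi) {
  t <- theta * pi / 180
  p <- phi * pi / 180
  rx <- matrix(c(1, 0, 0,
                 0, cos(t), sin(t),
                 0, -sin(t), cos(t)), 3, 3)  # column-major: maps y -> (0,cos t,sin t)
  rz <- matrix(c(cos(p), -sin(p), 0,
                 sin(p), cos(p), 0,
                 0, 0, 1), 3, 3)             # maps y -> (sin p, cos p, 0)
  rz %*% rx
}

# Unsigned angle (degrees) between two axial directions (sign-invariant,
# since orientation vectors are axes, not arrows).
axial_angle_deg <- function(a, b) {
  ca <- abs(sum(a * b)) / sqrt(sum(a^2) * sum(b^2))
  acos(min(1, ca)) * 180 / pi
}

# Wrap an angle difference into [-90, 90] (axial data).
wrap_axial_deg <- function(x) {
  x <- (x + 90) %% 180 - 90
  ifelse(x == -90, 90, x)
}
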