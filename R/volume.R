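#' Image volume container
#'
#' A `volume` wraps a 3D intensity array together with its physical voxel
#' size. Arrays are indexed `[z, y, x]`: the first index walks optical
#' planes, `y` is the longitudinal (traction) axis of the tissue strip and
#' `x` the transverse in-plane axis. Physical direction vectors elsewhere in
#' the package are written `(vx, vy, vz)`.
#'
#' @param data numeric 3D array, dimension `(nz, ny, nx)`. A matrix is
#'   promoted to a single-plane volume.
#' @param voxel numeric length-3, voxel size in micrometres as
#'   `(dz, dy, dx)`. The default matches a two-photon acquisition with
#'   0.44 um lateral pixels and a 2 um Z step.
#'
#' @return An object of class `volume`: a list with elements `data` and
#'   `voxel`.
#' @export
#'
#' @examples
#' v <- volume(array(0L, c(4, 16, 16)))
#' dim(v$data)
volume <- function(data, voxel = c(2, 0.44, 0.44)) {
  if (is.matrix(data)) data <- array(data, c(1L, dim(data)))
  stopifnot(is.array(data), length(dim(data)) == 3L, all(dim(data) >= 1L))
  voxel <- as.numeric(voxel)
  stopifnot(length(voxel) == 3L, all(voxel > 0))
  structure(list(data = data, voxel = voxel), class = "volume")
}

#' @export
print.volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<volume> %d x %d x %d voxels (z,y,x); voxel %.3g x %.3g x %.3g um; extent %.4g x %.4g x %.4g um\n",
    d[1], d[2], d[3], x$voxel[1], x$voxel[2], x$voxel[3],
    d[1] * x$voxel[1], d[2] * x$voxel[2], d[3] * x$voxel[3]
  ))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(x$data), max(x$data)))
  invisible(x)
}

#' Physical extent of a volume
#'
#' @param v a [volume()].
#' @return numeric length-3, extent in micrometres per `(z, y, x)` axis.
#' @export
volume_extent <- function(v) {
  stopifnot(inherits(v, "volume"))
  dim(v$data) * v$voxel
}

is_binary <- function(a) {
  u <- unique(as.vector(a))
  all(u %in% c(0, 1)) || all(u %in% c(0, 255)) || is.logical(a)
}

#' Binary segmentation mask
#'
#' Carrier for a Background/Tissue labelling aligned with a [volume()].
#' Stored logically; written to TIFF as 0/255.
#'
#' @param data logical (or 0/1, 0/255 numeric) array, same layout as the
#'   source volume.
#' @param voxel voxel size `(dz, dy, dx)` in micrometres.
#' @return An object of class `c("mask", "volume")` whose `data` is logical.
#' @export
mask_volume <- function(data, voxel = c(2, 0.44, 0.44)) {
  if (is.matrix(data)) data <- array(data, c(1L, dim(data)))
  stopifnot(is.array(data), length(dim(data)) == 3L)
  if (!is.logical(data)) {
    stopifnot(is_binary(data))
    data <- array(data > 0, dim(data))
  }
  v <- volume(array(data, dim(data)), voxel)
  class(v) <- c("mask", "volume")
  v
}
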