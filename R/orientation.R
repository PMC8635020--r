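# FFT-based orientation extraction. Z-bands repeat every 1.6-2.0 um along
# the myocyte long axis, so a chunk's 3D power spectrum shows a symmetric
# pair of peaks at that frequency; the peak direction IS the cell axis and
# its radius the inverse sarcomere period.

#' Chunk grid over a masked volume
#'
#' Tiles the volume with non-overlapping cubic chunks of physical side
#' `chunk_um` starting at the volume origin; partial chunks at the far edges
#' are discarded. Each chunk records the fraction of in-mask voxels and is
#' flagged `is_tissue` when that fraction reaches `tissue_fraction_min`.
#'
#' @param v a [volume()] (typically the masked, equalized stack).
#' @param mask a [mask_volume()] aligned to `v`, or `NULL` for all-tissue.
#' @param chunk_um chunk side in micrometres, default 16.
#' @param tissue_fraction_min minimum in-mask fraction, default 0.80.
#' @return tibble with one row per chunk: grid indices `iz, iy, ix`,
#'   voxel offsets, centre coordinates in micrometres, `tissue_fraction` and
#'   `is_tissue`; chunk voxel shape in attribute `chunk_px`.
#' @export
dissect_chunks <- function(v, mask = NULL, chunk_um = 16,
                           tissue_fraction_min = 0.80) {
  stopifnot(inherits(v, "volume"))
  d <- dim(v$data)
  cpx <- pmax(1L, as.integer(round(chunk_um / v$voxel)))  # (z, y, x)
  ng <- d %/% cpx
  if (any(ng < 1L)) stop("volume smaller than one chunk along some axis")
  if (!is.null(mask)) {
    stopifnot(inherits(mask, "mask"), all(dim(mask$data) == d))
    mdat <- mask$data
  } else {
    mdat <- NULL
  }
  grid <- tidyr::expand_grid(iz = seq_len(ng[1]), iy = seq_len(ng[2]),
                             ix = seq_len(ng[3]))
  off <- cbind((grid$iz - 1L) * cpx[1], (grid$iy - 1L) * cpx[2],
               (grid$ix - 1L) * cpx[3])
  frac <- if (is.null(mdat)) rep(1, nrow(grid)) else {
    vapply(seq_len(nrow(grid)), function(i) {
      mean(mdat[off[i, 1] + seq_len(cpx[1]),
                off[i, 2] + seq_len(cpx[2]),
                off[i, 3] + seq_len(cpx[3])])
    }, 0)
  }
  out <- dplyr::mutate(grid,
    z0 = off[, 1], y0 = off[, 2], x0 = off[, 3],
    zc_um = (.data$z0 + cpx[1] / 2) * v$voxel[1],
    yc_um = (.data$y0 + cpx[2] / 2) * v$voxel[2],
    xc_um = (.data$x0 + cpx[3] / 2) * v$voxel[3],
    tissue_fraction = frac,
    is_tissue = frac >= tissue_fraction_min
  )
  structure(out, chunk_px = cpx, grid_dim = as.integer(ng),
            class = class(out))
}

#' Zero-padded, centred chunk spectrum
#'
#' Computes the centred 3D FFT of a mean-subtracted chunk and zero-pads the
#' Z-frequency axis to a cubic grid, so the frequency lattice becomes (near)
#' isotropic: with 36 x 36 px at 0.44 um and 8 planes at 2 um, the padded
#' 36^3 grid has bins of 0.0631 (XY) vs 0.0625 (Z) inverse micrometres. Only
#' the original Z-frequency planes carry information; all other planes are
#' exactly zero, so spectral energy is conserved. Padding in frequency space
#' is equivalent to sinc interpolation of the chunk to an isotropic 0.44 um
#' voxel.
#'
#' @param chunk numeric 3D array `(nz, ny, nx)` with `ny == nx` and
#'   `nz <= ny`.
#' @return complex array of side `ny` (class `padded_spectrum` with the
#'   original `nz` in attribute `nz_orig`).
#' @export
pad_spectrum <- function(chunk) {
  stopifnot(is.array(chunk), length(dim(chunk)) == 3L)
  d <- dim(chunk)
  if (d[2] != d[3] || d[1] > d[2]) {
    stop("chunk must be (nz, n, n) with nz <= n; got ", paste(d, collapse = "x"))
  }
  n <- d[2]
  s <- fftshift3(fft(chunk - mean(chunk)))
  sp <- array(complex(real = 0), c(n, n, n))
  ctr_n <- n %/% 2 + 1L
  ctr_z <- d[1] %/% 2 + 1L
  sp[(ctr_n - ctr_z + 1L):(ctr_n - ctr_z + d[1]), , ] <- s
  structure(sp, nz_orig = d[1], class = "padded_spectrum")
}

#' Spherical-shell bandpass filter for the sarcomere frequency band
#'
#' Binary mask on the centred cubic frequency grid selecting voxels whose
#' Euclidean radius (in frequency bins) lies within the band of the sarcomere
#' periodicity. With the defaults (36^3 grid, 0.44 um pixels, 1.6-2.0 um
#' period) the bin size is 0.0631 um^-1 and the shell has mean radius
#' 0.556/0.0631 ~ 9 px between inner 8 px and outer 10 px.
#'
#' @param shape side of the cubic grid in px, default 36.
#' @param delta_f frequency-bin size in um^-1, default `1 / (36 * 0.44)`.
#' @param period_range_um sarcomere period band `(min, max)` in um.
#' @return list of class `shell_filter`: `mask` (logical array), `delta_f`,
#'   `rho`, `rho_inner`, `rho_outer` (px), `cutoff_um1` (mean-band frequency).
#' @export
make_shell_filter <- function(shape = 36L, delta_f = 1 / (36 * 0.44),
                              period_range_um = c(1.6, 2.0)) {
  stopifnot(delta_f > 0, length(period_range_um) == 2)
  if (period_range_um[1] >= period_range_um[2]) stop("period range inverted")
  cutoff <- 1 / mean(period_range_um)
  rho <- round(cutoff / delta_f)
  rho_m <- round((1 / period_range_um[2]) / delta_f)
  rho_M <- round((1 / period_range_um[1]) / delta_f)
  ctr <- shape %/% 2 + 1L
  ax <- (seq_len(shape) - ctr)^2
  r2 <- outer(outer(ax, ax, "+"), ax, "+")
  mask <- (r2 >= rho_m^2) & (r2 <= rho_M^2)
  structure(list(mask = mask, shape = as.integer(shape), delta_f = delta_f,
                 rho = rho, rho_inner = rho_m, rho_outer = rho_M,
                 cutoff_um1 = cutoff),
            class = "shell_filter")
}

#' Smoothed total and in-band power spectral densities
#'
#' `Sxx = |S'|^2` and `Sxxf = |filter * S'|^2`, each convolved with a
#' normalized 3 x 3 x 3 Gaussian kernel (sigma 0.8 px, reflect padding):
#' by the convolution theorem this applies a radial apodization of the chunk,
#' damping boundary leakage.
#'
#' @param spectrum a [pad_spectrum()] result.
#' @param filter a [make_shell_filter()] with matching shape.
#' @return list with arrays `sxx` and `sxxf` (both >= 0) and the spectrum
#'   centre index `center`.
#' @export
smoothed_psds <- function(spectrum, filter) {
  stopifnot(inherits(filter, "shell_filter"))
  d <- dim(spectrum)
  if (!all(d == filter$shape)) stop("spectrum/filter shape mismatch")
  sxx <- Mod(spectrum)^2
  sxxf <- sxx * filter$mask
  list(sxx = gaussian_smooth_3d(sxx, rep(0.8, 3), radius = 1L),
       sxxf = gaussian_smooth_3d(sxxf, rep(0.8, 3), radius = 1L),
       center = d %/% 2L + 1L)
}

#' Z-band signal-to-noise score of one chunk
#'
#' Ratio of in-band spectral energy to total spectral energy, the reliability
#' score of the chunk's Z-band periodicity. The DC bin is excluded from the
#' denominator so the score reflects structure rather than mean brightness
#' (the chunk mean is already subtracted in [pad_spectrum()]).
#'
#' @param psds a [smoothed_psds()] result.
#' @return scalar in `[0, 1]`, or `NA` for an all-zero spectrum.
#' @export
sratio <- function(psds) {
  ctr <- psds$center
  total <- sum(psds$sxx) - psds$sxx[ctr[1], ctr[2], ctr[3]]
  if (total <= 0) return(NA_real_)
  min(1, sum(psds$sxxf) / total)
}

#' Peak localization in the filtered spectrum
#'
#' The orientation is read off the in-band spectral peak: the maximum voxel
#' of the filtered PSD is refined to sub-bin precision by the intensity
#' centroid of the 4 x 4 x 4 window anchored one voxel before the maximum
#' (clipped at grid edges). The vector from the spectrum centre to the
#' centroid gives the myocyte axis; its length times `delta_f` is the Z-band
#' spatial frequency. Vectors are flipped into the `vy >= 0` hemisphere
#' (ties: `vx >= 0`), exploiting the spectrum's central symmetry.
#'
#' @param sxxf smoothed filtered PSD array (from [smoothed_psds()]).
#' @param delta_f frequency-bin size in um^-1.
#' @return list: `direction` (unit `(vx, vy, vz)`), `frequency_um1`,
#'   `period_um`; or `NULL` if the filtered PSD is all zero.
#' @export
extract_orientation <- function(sxxf, delta_f = 1 / (36 * 0.44)) {
  if (max(sxxf) <= 0) return(NULL)
  d <- dim(sxxf)
  ctr <- d %/% 2L + 1L
  vmax <- arrayInd(which.max(sxxf), d)[1, ]
  lo <- pmax(vmax - 1L, 1L)
  hi <- pmin(lo + 3L, d)
  lo <- pmax(hi - 3L, 1L)
  w <- sxxf[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]]
  tot <- sum(w)
  cz <- sum(rowSums(w) * (lo[1]:hi[1])) / tot
  cy <- sum(apply(w, 2, sum) * (lo[2]:hi[2])) / tot
  cx <- sum(apply(w, 3, sum) * (lo[3]:hi[3])) / tot
  v <- c(cx - ctr[3], cy - ctr[2], cz - ctr[1])   # (vx, vy, vz) in bins
  r <- sqrt(sum(v^2))
  if (r == 0) return(NULL)
  if (v[2] < 0 || (v[2] == 0 && v[1] < 0)) v <- -v
  freq <- r * delta_f
  list(direction = v / r, frequency_um1 = freq, period_um = 1 / freq)
}

#' Min-max normalization of Sratio and reliability flagging
#'
#' Raw Sratio values of the tissue chunks of one sample are normalized to
#' `[0, 1]` by min-max; a chunk is reliable when its normalized score exceeds
#' `threshold`. Because min-max is relative to the sample, an optional
#' absolute floor on the raw score (`raw_floor`) additionally rejects chunks
#' whose in-band energy is indistinguishable from a flat (structureless)
#' spectrum — [analyze_volume()] sets it to twice the shell's share of the
#' informative spectrum. If all raw scores coincide the normalized scores are
#' all 0 (with a warning) and nothing is reliable.
#'
#' @param field a `vector_field` tibble with raw scores.
#' @param threshold reliability threshold on the normalized score,
#'   default 0.14.
#' @param raw_floor minimum raw Sratio for reliability, default 0 (off).
#' @return the field with `sratio_norm` and `is_reliable` filled in.
#' @export
normalize_sratio <- function(field, threshold = 0.14, raw_floor = 0) {
  raw <- field$sratio_raw[field$is_tissue & !is.na(field$sratio_raw)]
  if (!length(raw)) {
    field$sratio_norm <- NA_real_
    field$is_reliable <- FALSE
    return(field)
  }
  rng <- range(raw)
  if (rng[1] == rng[2]) {
    warning("all raw Sratio values equal; normalized scores set to 0")
    field$sratio_norm <- ifelse(field$is_tissue, 0, NA_real_)
  } else {
    field$sratio_norm <- ifelse(field$is_tissue,
                                (field$sratio_raw - rng[1]) / (rng[2] - rng[1]),
                                NA_real_)
  }
  field$is_reliable <- !is.na(field$sratio_norm) &
    field$sratio_norm > threshold &
    field$sratio_raw > raw_floor &
    !is.na(field$vx)
  field
}

#' Neighborhood-consistency outlier removal
#'
#' Each reliable vector is compared with the mean direction of its reliable
#' 26-neighborhood: a vector deviating by more than `angle_max` degrees must
#' justify itself with a normalized Sratio above `2 * base_threshold`,
#' otherwise it is flagged an outlier and dropped from the reliable set.
#' Single pass over the original flags; records without reliable neighbors
#' are kept unchanged.
#'
#' @param field a normalized `vector_field`.
#' @param base_threshold the reliability threshold in force, default 0.14.
#' @param angle_max angular deviation tolerated without extra evidence,
#'   degrees, default 45.
#' @return the field with `is_outlier` set and `is_reliable` updated.
#' @export
remove_outliers <- function(field, base_threshold = 0.14, angle_max = 45) {
  gd <- attr(field, "grid_dim")
  rel0 <- field$is_reliable
  field$is_outlier <- FALSE
  if (!any(rel0)) return(field)
  # index cube of reliable vectors for O(1) neighborhood lookup
  key <- array(0L, gd)
  key[cbind(field$iz, field$iy, field$ix)] <- seq_len(nrow(field))
  vs <- cbind(field$vx, field$vy, field$vz)
  offs <- as.matrix(tidyr::expand_grid(dz = -1:1, dy = -1:1, dx = -1:1))
  offs <- offs[rowSums(offs != 0) > 0, ]
  for (i in which(rel0)) {
    nb <- cbind(field$iz[i] + offs[, 1], field$iy[i] + offs[, 2],
                field$ix[i] + offs[, 3])
    ok <- nb[, 1] >= 1 & nb[, 1] <= gd[1] & nb[, 2] >= 1 & nb[, 2] <= gd[2] &
      nb[, 3] >= 1 & nb[, 3] <= gd[3]
    ids <- key[nb[ok, , drop = FALSE]]
    ids <- ids[ids > 0 & rel0[ids]]
    if (!length(ids)) next
    mdir <- colMeans(vs[ids, , drop = FALSE])
    if (sqrt(sum(mdir^2)) == 0) next
    dev <- axial_angle_deg(vs[i, ], mdir)
    if (dev > angle_max && field$sratio_norm[i] <= 2 * base_threshold) {
      field$is_outlier[i] <- TRUE
      field$is_reliable[i] <- FALSE
    }
  }
  field
}

orient_one_chunk <- function(chunk, filter) {
  sp <- pad_spectrum(chunk)
  ps <- smoothed_psds(sp, filter)
  sc <- sratio(ps)
  or <- extract_orientation(ps$sxxf, filter$delta_f)
  list(sratio = sc, orientation = or)
}

#' Full orientation analysis of a masked volume
#'
#' Orchestrates the frequency pipeline: chunk dissection, per-chunk padded
#' spectrum, shell filtering, smoothed PSDs, Sratio, peak extraction, sample
#' -wide Sratio normalization and neighborhood outlier removal.
#'
#' @param v masked, equalized [volume()].
#' @param mask [mask_volume()] or `NULL` to treat everything as tissue
#'   (useful for synthetic samples that need no segmentation).
#' @param config a [run_config()].
#' @param verbose log stage counts, default `FALSE`.
#' @return A `vector_field` tibble (one row per chunk) with attributes
#'   `grid_dim`, `chunk_um`, `voxel` and `counts`.
#' @export
analyze_volume <- function(v, mask = NULL, config = run_config(),
                           verbose = FALSE) {
  chunks <- dissect_chunks(v, mask, config$chunk_um,
                           config$tissue_fraction_min)
  cpx <- attr(chunks, "chunk_px")
  gd <- attr(chunks, "grid_dim")
  delta_f <- 1 / (cpx[2] * v$voxel[2])
  filter <- make_shell_filter(cpx[2], delta_f, config$period_range_um)
  n <- nrow(chunks)
  vx <- vy <- vz <- freq <- per <- raw <- rep(NA_real_, n)
  idx_t <- which(chunks$is_tissue)
  for (i in idx_t) {
    ch <- v$data[chunks$z0[i] + seq_len(cpx[1]),
                 chunks$y0[i] + seq_len(cpx[2]),
                 chunks$x0[i] + seq_len(cpx[3])]
    r <- orient_one_chunk(ch, filter)
    raw[i] <- r$sratio
    if (!is.null(r$orientation)) {
      vx[i] <- r$orientation$direction[1]
      vy[i] <- r$orientation$direction[2]
      vz[i] <- r$orientation$direction[3]
      freq[i] <- r$orientation$frequency_um1
      per[i] <- r$orientation$period_um
    }
  }
  chunks$is_tissue[idx_t[is.na(raw[idx_t])]] <- FALSE  # degenerate spectra
  field <- dplyr::mutate(chunks,
    vx = vx, vy = vy, vz = vz,
    frequency_um1 = freq, period_um = per,
    sratio_raw = raw, sratio_norm = NA_real_,
    is_reliable = FALSE, is_outlier = FALSE)
  field <- new_vector_field(field, grid_dim = gd, chunk_um = config$chunk_um,
                            voxel = v$voxel)
  if (!any(field$is_tissue)) {
    warning("no tissue chunks found; empty vector field")
    attr(field, "counts") <- c(total = n, tissue = 0, reliable = 0, outlier = 0)
    return(field)
  }
  # flat-spectrum baseline: the shell's share of the informative Z planes
  ctr_n <- cpx[2] %/% 2 + 1L
  ctr_z <- cpx[1] %/% 2 + 1L
  zrows <- (ctr_n - ctr_z + 1L):(ctr_n - ctr_z + cpx[1])
  flat_share <- sum(filter$mask[zrows, , ]) / prod(cpx)
  field <- normalize_sratio(field, config$sratio_threshold,
                            raw_floor = 2 * flat_share)
  field <- remove_outliers(field, config$sratio_threshold)
  counts <- c(total = n, tissue = sum(field$is_tissue),
              reliable = sum(field$is_reliable),
              outlier = sum(field$is_outlier))
  attr(field, "counts") <- counts
  if (verbose) {
    message(sprintf("chunks: %d total, %d tissue, %d reliable, %d outliers",
                    counts[1], counts[2], counts[3], counts[4]))
  }
  field
}
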