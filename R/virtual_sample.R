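# Virtual tissue samples: lattices of virtual cardiomyocytes cut from a
# striated base volume, each rotated by angles drawn from normal
# distributions. Sweeping the angular dispersion calibrates the disarray
# statistic against true cell misalignment.

#' Specification of a virtual tissue sample
#'
#' @param sample_um sample extent in micrometres, order `(y, x, z)` — the
#'   strip's long (traction) axis first. Default `c(1300, 400, 280)`.
#' @param cell_um virtual-cardiomyocyte extent `(y, x, z)`, long axis Y,
#'   default `c(80, 20, 20)`.
#' @param base_um extent `(y, x, z)` of the representative base volume the
#'   cells are cut from, default `c(80, 80, 66)`.
#' @param theta_mean,phi_mean mean cell orientation in degrees (0, 0 keeps
#'   the sample aligned with the traction axis).
#' @param sigma_theta,sigma_phi angular dispersion (SD of the per-cell normal
#'   draws) in degrees; 0 means uniform alignment, i.e. no disarray.
#' @param voxel voxel size `(dz, dy, dx)` um, default `c(2, 0.44, 0.44)`.
#' @param psf_sigma_z_um,psf_sigma_xy_um PSF sigmas; rotated bases are
#'   re-blurred along Z with `sqrt(sigma_z^2 - sigma_xy^2)`.
#' @param border_sigma_px Gaussian sigma (voxels) smoothing cell borders in
#'   the assembled sample, default 1.
#' @param period_um sarcomere period of the default synthetic base.
#' @param base optional user [volume()] to use as base (Z-band signal aligned
#'   with +Y); `NULL` builds a synthetic striated base.
#' @param seed integer seed governing the per-cell angle draws.
#' @return list of class `virtual_sample_spec`.
#' @export
virtual_sample_spec <- function(sample_um = c(1300, 400, 280),
                                cell_um = c(80, 20, 20),
                                base_um = c(80, 80, 66),
                                theta_mean = 0, phi_mean = 0,
                                sigma_theta = 0, sigma_phi = 0,
                                voxel = c(2, 0.44, 0.44),
                                psf_sigma_z_um = 1.316,
                                psf_sigma_xy_um = 0.25,
                                border_sigma_px = 1,
                                period_um = 1.8,
                                base = NULL,
                                seed = 1L) {
  stopifnot(sigma_theta >= 0, sigma_phi >= 0, all(sample_um > 0),
            all(cell_um > 0), all(base_um >= cell_um))
  # the rotated cell must stay inside the base for draws up to ~3 sigma
  max_rot <- max(abs(theta_mean) + 3 * sigma_theta,
                 abs(phi_mean) + 3 * sigma_phi)
  half_need <- (cell_um[1] / 2) * cos(pmin(max_rot, 90) * pi / 180) +
    (cell_um[2] / 2) * sin(pmin(max_rot, 90) * pi / 180)
  if (half_need > base_um[1] / 2 + 1e-9 && max_rot > 0) {
    warning("cell may leave the base for rotations up to 3 sigma")
  }
  structure(as.list(environment()), class = "virtual_sample_spec")
}

default_base <- function(spec) {
  make_striated_volume(phantom_spec(
    extent_um = spec$base_um[c(3, 1, 2)],  # (z, y, x)
    voxel = spec$voxel, period_um = spec$period_um,
    theta = 0, phi = 0, noise_sd = 5,
    sigma_z_um = spec$psf_sigma_xy_um,     # sharp base; axial PSF added per cell
    sigma_xy_um = spec$psf_sigma_xy_um,
    seed = spec$seed
  ))$volume
}

#' Build one virtual cardiomyocyte
#'
#' Rotates the base by `(theta, phi)` about its centre, applies the residual
#' axial blur `sigma_k = sqrt(sigma_z^2 - sigma_xy^2)` along Z (simulating
#' the optical system seeing the rotated cell), and extracts the central
#' `cell_um` crop.
#'
#' @param base a [volume()] with Z-band signal aligned with +Y.
#' @param theta,phi cell rotation in degrees.
#' @param cell_um crop extent `(y, x, z)` um, default `c(80, 20, 20)`.
#' @param psf_sigma_z_um,psf_sigma_xy_um PSF sigmas in um; an error is raised
#'   if `psf_sigma_z_um <= psf_sigma_xy_um` (residual blur undefined).
#' @return numeric array `(nz, ny, nx)` of the cell.
#' @export
make_virtual_cell <- function(base, theta, phi,
                              cell_um = c(80, 20, 20),
                              psf_sigma_z_um = 1.316,
                              psf_sigma_xy_um = 0.25) {
  stopifnot(inherits(base, "volume"))
  if (psf_sigma_z_um <= psf_sigma_xy_um) {
    stop("psf_sigma_z_um must exceed psf_sigma_xy_um (residual axial blur)")
  }
  sk <- sqrt(psf_sigma_z_um^2 - psf_sigma_xy_um^2)
  cell_px <- pmax(1L, as.integer(round(cell_um[c(3, 1, 2)] / base$voxel)))
  pad <- ceiling(3 * sk / base$voxel[1])
  ch <- rotate_and_extract_chunk(base, theta, phi,
                                 chunk_px = cell_px + c(2L * pad, 0L, 0L),
                                 out_voxel = base$voxel,
                                 psf_sigma_z_um = 0)
  ch <- gaussian_smooth_3d(ch, c(sk / base$voxel[1], 0, 0))
  ch[pad + seq_len(cell_px[1]), , , drop = FALSE]
}

#' Generate a virtual tissue sample
#'
#' Tiles the sample extent with a gapless, axis-aligned lattice of virtual
#' cells (the extent is truncated to whole cells, with a warning when that
#' loses space), draws each cell's `(theta, phi)` independently from
#' `N(theta_mean, sigma_theta)` and `N(phi_mean, sigma_phi)`, builds the
#' cells with [make_virtual_cell()] from one shared base, and smooths the
#' assembled volume with a Gaussian of `border_sigma_px` voxels before 8-bit
#' quantization.
#'
#' @param spec a [virtual_sample_spec()].
#' @return list of class `virtual_sample`: `volume` (8-bit [volume()]) and
#'   `truth` (tibble: cell lattice indices, centre um, `theta`, `phi`,
#'   ground-truth direction `(vx, vy, vz)`).
#' @export
generate_sample <- function(spec) {
  stopifnot(inherits(spec, "virtual_sample_spec"))
  base <- spec$base %||% default_base(spec)
  cell_px <- pmax(1L, as.integer(round(spec$cell_um[c(3, 1, 2)] / spec$voxel)))
  nlat <- as.integer(floor(spec$sample_um / spec$cell_um))  # (y, x, z)
  if (any(nlat < 1L)) stop("sample extent smaller than one cell")
  if (any(abs(nlat * spec$cell_um - spec$sample_um) > 1e-9)) {
    warning("sample extent truncated to a whole-cell lattice: ",
            paste(nlat * spec$cell_um, collapse = " x "), " um (y, x, z)")
  }
  dims <- cell_px * nlat[c(3, 1, 2)]                        # (z, y, x)
  set.seed(spec$seed)
  lat <- tidyr::expand_grid(cy = seq_len(nlat[1]), cx = seq_len(nlat[2]),
                            cz = seq_len(nlat[3]))
  lat$theta <- rnorm(nrow(lat), spec$theta_mean, spec$sigma_theta)
  lat$phi <- rnorm(nrow(lat), spec$phi_mean, spec$sigma_phi)
  a <- array(0, dims)
  for (i in seq_len(nrow(lat))) {
    cell <- make_virtual_cell(base, lat$theta[i], lat$phi[i],
                              cell_um = spec$cell_um,
                              psf_sigma_z_um = spec$psf_sigma_z_um,
                              psf_sigma_xy_um = spec$psf_sigma_xy_um)
    a[(lat$cz[i] - 1L) * cell_px[1] + seq_len(cell_px[1]),
      (lat$cy[i] - 1L) * cell_px[2] + seq_len(cell_px[2]),
      (lat$cx[i] - 1L) * cell_px[3] + seq_len(cell_px[3])] <- cell
  }
  if (spec$border_sigma_px > 0) {
    a <- gaussian_smooth_3d(a, rep(spec$border_sigma_px, 3))
  }
  a <- array(pmin(255, pmax(0, round(a))), dims)
  dirs <- t(mapply(dir_from_angles, lat$theta, lat$phi))
  truth <- dplyr::mutate(lat,
    yc_um = (.data$cy - 0.5) * spec$cell_um[1],
    xc_um = (.data$cx - 0.5) * spec$cell_um[2],
    zc_um = (.data$cz - 0.5) * spec$cell_um[3],
    vx = dirs[, 1], vy = dirs[, 2], vz = dirs[, 3]
  )
  structure(list(volume = volume(a, spec$voxel), truth = truth, spec = spec),
            class = "virtual_sample")
}

#' @export
print.virtual_sample <- function(x, ...) {
  d <- dim(x$volume$data)
  cat(sprintf(
    "<virtual_sample> %d cells; sigma_theta = %g, sigma_phi = %g deg; volume %d x %d x %d voxels\n",
    nrow(x$truth), x$spec$sigma_theta, x$spec$sigma_phi, d[1], d[2], d[3]))
  invisible(x)
}

#' Disarray response to cell angular dispersion
#'
#' For each dispersion value, generates a virtual sample with
#' `sigma_theta = sigma_phi = sigma`, runs the orientation pipeline (no
#' segmentation: the whole sample is tissue) and the disarray analysis at the
#' stated resolution, and fits the local disarray distribution.
#'
#' @param sigma_list angular dispersions in degrees.
#' @param analysis_resolution_um macrovoxel side, default 64 (m = 4 at 16 um
#'   chunks).
#' @param seed base seed; sample `i` uses `seed + i` so each dispersion has a
#'   fixed, reproducible sample.
#' @param spec template [virtual_sample_spec()] supplying everything except
#'   the dispersions and seed.
#' @param config a [run_config()].
#' @return tibble: `sigma`, `side_um`, `N_v`, `D`, `A`, `mode`, `std_dev`,
#'   `lognormal_p`.
#' @export
dispersion_sweep <- function(sigma_list, analysis_resolution_um = 64,
                             seed = 1L, spec = virtual_sample_spec(),
                             config = run_config(seed = seed)) {
  stopifnot(length(sigma_list) >= 1)
  m <- as.integer(round(analysis_resolution_um / config$chunk_um))
  purrr::imap_dfr(sigma_list, function(sg, i) {
    sp <- spec
    sp$sigma_theta <- sg
    sp$sigma_phi <- sg
    sp$seed <- as.integer(seed + i)
    vs <- generate_sample(sp)
    field <- analyze_volume(vs$volume, mask = NULL, config = config)
    dm <- disarray_map(field, m)
    fit <- suppressWarnings(fit_lognormal(dm$d[dm$valid]))
    tibble::tibble(sigma = sg, side_um = attr(dm, "side_um"),
                   N_v = attr(dm, "N_v"), D = attr(dm, "D"),
                   A = attr(dm, "A"), mu = fit$mu, ln_sigma = fit$sigma,
                   mode = fit$mode, std_dev = fit$std_dev,
                   lognormal_p = fit$p_value)
  })
}

#' Match an observed disarray distribution to a cell dispersion
#'
#' Simulates a virtual sample for every candidate dispersion, fits its local
#' disarray distribution at the stated resolution and returns the candidate
#' whose fitted PDF is closest (L2 distance on a fixed disarray grid,
#' 0-50% in 500 points) to the observed fit.
#'
#' @param observed_fit a [fit_lognormal()] of the observed LDD.
#' @param sigma_candidates candidate dispersions in degrees.
#' @param resolution_um macrovoxel side for the simulated LDDs, default 64.
#' @param seed base seed for the simulations.
#' @param spec,config as in [dispersion_sweep()].
#' @return list: `best_sigma`, `distances` (tibble of candidate, distance,
#'   mu, sigma).
#' @export
match_dispersion <- function(observed_fit, sigma_candidates,
                             resolution_um = 64, seed = 1L,
                             spec = virtual_sample_spec(),
                             config = run_config(seed = seed)) {
  stopifnot(inherits(observed_fit, "lognormal_fit"),
            length(sigma_candidates) >= 1, is.finite(observed_fit$mu))
  grid <- seq(0, 50, length.out = 500)[-1]
  obs_pdf <- dlnorm(grid, observed_fit$mu, observed_fit$sigma)
  sweep_tb <- dispersion_sweep(sigma_candidates, resolution_um, seed,
                               spec, config)
  dist <- purrr::map2_dbl(sweep_tb$mu, sweep_tb$ln_sigma, function(mu, sg) {
    if (!is.finite(mu)) return(Inf)
    sim_pdf <- dlnorm(grid, mu, sg)
    sqrt(sum((sim_pdf - obs_pdf)^2) * diff(grid[1:2]))
  })
  out <- tibble::tibble(sigma = sigma_candidates, distance = dist)
  list(best_sigma = sigma_candidates[which.min(dist)], distances = out,
       sweep = sweep_tb)
}
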