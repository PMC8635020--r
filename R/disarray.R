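# Disarray statistics: macrovoxel aggregation of orientation vectors into
# local disarray / alignment, global summaries, log-normal fits of the local
# disarray distribution (LDD) and rendered 3D maps.

#' Local disarray of a set of orientation vectors
#'
#' One minus the mean resultant length of the unit vectors, as a percentage:
#' 0% for perfectly aligned vectors, approaching 100% for balanced opposing
#' directions. Since every vector lives in the `vy >= 0` hemisphere, purely
#' random orientations give ~50%.
#'
#' @param v numeric matrix, one unit vector `(vx, vy, vz)` per row.
#' @return disarray in percent.
#' @export
#' @examples
#' local_disarray(rbind(c(0, 1, 0), c(1, 0, 0)))  # 29.289
local_disarray <- function(v) {
  v <- rbind(v)
  if (nrow(v) < 1) stop("need at least one vector")
  nrm <- sqrt(rowSums(v^2))
  if (any(nrm == 0)) stop("zero-length orientation vector")
  u <- v / nrm
  (1 - sqrt(sum(colMeans(u)^2))) * 100
}

#' Local alignment with the traction axis
#'
#' Mean Y component of the unit orientation vectors: 1 when everything points
#' along the strip's longitudinal axis, 0 when orthogonal to it.
#'
#' @inheritParams local_disarray
#' @return alignment in `[0, 1]` (the hemisphere flip guarantees `vy >= 0`).
#' @export
local_alignment <- function(v) {
  v <- rbind(v)
  if (nrow(v) < 1) stop("need at least one vector")
  nrm <- sqrt(rowSums(v^2))
  if (any(nrm == 0)) stop("zero-length orientation vector")
  mean(v[, 2] / nrm)
}

#' Macrovoxel disarray map at one spatial scale
#'
#' Tiles the vector grid with non-overlapping macrovoxels of `m` vectors per
#' side (physical side `m * chunk_um`; partial macrovoxels at the far edges
#' are discarded). A macrovoxel is valid when at least half of its `m^3`
#' slots hold reliable vectors; local disarray and alignment are computed on
#' the reliable vectors of each valid macrovoxel, and the global disarray `D`
#' and alignment `A` are their arithmetic means over the `N_v` valid
#' macrovoxels.
#'
#' @param field a `vector_field` from [analyze_volume()].
#' @param m vectors per macrovoxel side (2-6 covers 32-96 um sides at the
#'   default chunk).
#' @param valid_fraction_min minimum reliable-slot fraction, default 0.5.
#' @return tibble of class `disarray_map`, one row per macrovoxel (`gz, gy,
#'   gx`, centre coordinates, `n_reliable`, `valid`, `d` %, `a`), with
#'   attributes `m`, `side_um`, `D`, `A`, `N_v`, `grid_dim`.
#' @export
disarray_map <- function(field, m, valid_fraction_min = 0.5) {
  stopifnot(inherits(field, "vector_field"), m >= 2)
  m <- as.integer(m)
  gd <- attr(field, "grid_dim")
  chunk_um <- attr(field, "chunk_um")
  mg <- gd %/% m
  if (any(mg < 1L)) stop("vector field smaller than one macrovoxel")
  gidx <- cbind((field$iz - 1L) %/% m, (field$iy - 1L) %/% m,
                (field$ix - 1L) %/% m)
  inside <- gidx[, 1] < mg[1] & gidx[, 2] < mg[2] & gidx[, 3] < mg[3]
  df <- tibble::tibble(
    gz = gidx[inside, 1] + 1L, gy = gidx[inside, 2] + 1L,
    gx = gidx[inside, 3] + 1L,
    vx = field$vx[inside], vy = field$vy[inside], vz = field$vz[inside],
    rel = field$is_reliable[inside]
  )
  per <- df |>
    dplyr::group_by(.data$gz, .data$gy, .data$gx) |>
    dplyr::summarise(
      n_reliable = sum(.data$rel),
      valid = sum(.data$rel) >= valid_fraction_min * m^3,
      d = if (sum(.data$rel) > 0)
        local_disarray(cbind(.data$vx, .data$vy, .data$vz)[.data$rel, , drop = FALSE])
      else NA_real_,
      a = if (sum(.data$rel) > 0)
        local_alignment(cbind(.data$vx, .data$vy, .data$vz)[.data$rel, , drop = FALSE])
      else NA_real_,
      .groups = "drop"
    ) |>
    dplyr::mutate(
      d = ifelse(.data$valid, .data$d, NA_real_),
      a = ifelse(.data$valid, .data$a, NA_real_),
      zc_um = (.data$gz - 0.5) * m * chunk_um,
      yc_um = (.data$gy - 0.5) * m * chunk_um,
      xc_um = (.data$gx - 0.5) * m * chunk_um
    )
  nv <- sum(per$valid)
  structure(per,
            m = m, side_um = m * chunk_um,
            D = if (nv > 0) mean(per$d[per$valid]) else NA_real_,
            A = if (nv > 0) mean(per$a[per$valid]) else NA_real_,
            N_v = nv, grid_dim = mg, chunk_um = chunk_um,
            class = c("disarray_map", class(per)))
}

#' @export
print.disarray_map <- function(x, ...) {
  cat(sprintf("<disarray_map> m = %d (%g um side); N_v = %d; D = %.3g%%; A = %.3g\n",
              attr(x, "m"), attr(x, "side_um"), attr(x, "N_v"),
              attr(x, "D"), attr(x, "A")))
  NextMethod()
}

#' D'Agostino-Pearson omnibus normality test
#'
#' Combines the standard normal transforms of sample skewness (D'Agostino)
#' and kurtosis (Anscombe-Glynn) into `K2 = Z1^2 + Z2^2`, referred to a
#' chi-squared distribution with 2 degrees of freedom.
#'
#' @param x numeric vector, `n >= 20` recommended (the kurtosis transform is
#'   an approximation for small n).
#' @return list with `statistic` (K2), `p_value`, `z_skew`, `z_kurt`, `n`.
#' @export
dagostino_pearson <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 8) stop("D'Agostino-Pearson test needs n >= 8")
  mu <- mean(x)
  m2 <- mean((x - mu)^2)
  m3 <- mean((x - mu)^3)
  m4 <- mean((x - mu)^4)
  g1 <- m3 / m2^1.5
  b2 <- m4 / m2^2
  # skewness transform (D'Agostino 1970)
  y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(0.5 * log(w2))
  alpha <- sqrt(2 / (w2 - 1))
  z1 <- delta * log(y / alpha + sqrt((y / alpha)^2 + 1))
  # kurtosis transform (Anscombe & Glynn 1983)
  eb2 <- 3 * (n - 1) / (n + 1)
  vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xk <- (b2 - eb2) / sqrt(vb2)
  sqrtb1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  a <- 6 + 8 / sqrtb1 * (2 / sqrtb1 + sqrt(1 + 4 / sqrtb1^2))
  z2 <- ((1 - 2 / (9 * a)) -
           ((1 - 2 / a) / (1 + xk * sqrt(2 / (a - 4))))^(1 / 3)) /
    sqrt(2 / (9 * a))
  k2 <- z1^2 + z2^2
  list(statistic = k2, p_value = pchisq(k2, df = 2, lower.tail = FALSE),
       z_skew = z1, z_kurt = z2, n = n)
}

#' Log-normal fit of a local disarray distribution
#'
#' Fits `ln d ~ Normal(mu, sigma)` by moment matching on the log scale (the
#' maximum-likelihood estimate for a log-normal), derives the PDF mode
#' `exp(mu - sigma^2)` and standard deviation
#' `sqrt((exp(sigma^2) - 1) * exp(2 mu + sigma^2))`, and tests log-normality
#' with the D'Agostino-Pearson omnibus test applied to `ln d`. Non-positive
#' values (perfectly aligned macrovoxels) are excluded and counted.
#'
#' @param d numeric vector of local disarray values (percent).
#' @param min_n minimum number of positive values required, default 20.
#' @return object of class `lognormal_fit`: `mu`, `sigma`, `mode`, `std_dev`,
#'   `statistic`, `p_value`, `n_used`, `n_excluded`.
#' @export
fit_lognormal <- function(d, min_n = 20L) {
  d <- d[is.finite(d)]
  pos <- d[d > 0]
  n_exc <- length(d) - length(pos)
  if (length(pos) < min_n) {
    warning("fewer than ", min_n, " positive values; fit refused")
    return(structure(list(mu = NA_real_, sigma = NA_real_, mode = NA_real_,
                          std_dev = NA_real_, statistic = NA_real_,
                          p_value = NA_real_, n_used = length(pos),
                          n_excluded = n_exc),
                     class = "lognormal_fit"))
  }
  lx <- log(pos)
  mu <- mean(lx)
  sigma <- sd(lx)
  dp <- dagostino_pearson(lx)
  structure(list(
    mu = mu, sigma = sigma,
    mode = exp(mu - sigma^2),
    std_dev = sqrt((exp(sigma^2) - 1) * exp(2 * mu + sigma^2)),
    statistic = dp$statistic, p_value = dp$p_value,
    n_used = length(pos), n_excluded = n_exc
  ), class = "lognormal_fit")
}

#' @export
print.lognormal_fit <- function(x, ...) {
  cat(sprintf(
    "<lognormal_fit> mu = %.4g, sigma = %.4g | mode = %.4g, sd = %.4g | K2 = %.3g (p = %.3g), n = %d (+%d excluded)\n",
    x$mu, x$sigma, x$mode, x$std_dev, x$statistic, x$p_value,
    x$n_used, x$n_excluded))
  invisible(x)
}

#' Multi-resolution disarray summary
#'
#' Runs [disarray_map()] and [fit_lognormal()] for every macrovoxel scale in
#' `m_list` and collects the global statistics in one table.
#'
#' @param field a `vector_field`.
#' @param m_list macrovoxel sides in vectors, default `2:6`.
#' @param min_n minimum LDD size for fitting, passed to [fit_lognormal()].
#' @return tibble: `m`, `side_um`, `N_v`, `D`, `A`, `mode`, `std_dev`,
#'   `lognormal_p`.
#' @export
multiresolution_table <- function(field, m_list = 2:6, min_n = 20L) {
  if (!any(field$is_reliable)) {
    warning("no reliable vectors; empty multiresolution table")
    return(tibble::tibble(m = integer(), side_um = double(), N_v = integer(),
                          D = double(), A = double(), mode = double(),
                          std_dev = double(), lognormal_p = double()))
  }
  purrr::map_dfr(m_list, function(m) {
    dm <- disarray_map(field, m)
    fit <- suppressWarnings(fit_lognormal(dm$d[dm$valid], min_n = min_n))
    tibble::tibble(m = as.integer(m), side_um = attr(dm, "side_um"),
                   N_v = attr(dm, "N_v"), D = attr(dm, "D"),
                   A = attr(dm, "A"), mode = fit$mode,
                   std_dev = fit$std_dev, lognormal_p = fit$p_value)
  })
}

#' Render a smoothed 3D disarray volume
#'
#' Paints each valid macrovoxel's disarray into a voxel grid at macrovoxel
#' resolution, upsamples (nearest) to chunk resolution and smooths with an
#' isotropic Gaussian of `sigma_um`; invalid regions render as 0. The result
#' can be written as a 32-bit float TIFF with [write_volume()].
#'
#' @param map a [disarray_map()].
#' @param sigma_um smoothing sigma in micrometres, default 10; 0 gives the
#'   raw block map.
#' @return a [volume()] at chunk resolution (voxel = chunk side).
#' @export
render_disarray_volume <- function(map, sigma_um = 10) {
  stopifnot(inherits(map, "disarray_map"))
  if (!any(map$valid)) stop("map has no valid macrovoxel")
  m <- attr(map, "m")
  mg <- attr(map, "grid_dim")
  chunk_um <- attr(map, "chunk_um")
  a <- array(0, mg)
  ok <- map$valid
  a[cbind(map$gz[ok], map$gy[ok], map$gx[ok])] <- map$d[ok]
  up <- a[rep(seq_len(mg[1]), each = m),
          rep(seq_len(mg[2]), each = m),
          rep(seq_len(mg[3]), each = m)]
  if (sigma_um > 0) {
    up <- gaussian_smooth_3d(up, rep(sigma_um / chunk_um, 3))
  }
  volume(up, voxel = rep(chunk_um, 3))
}
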