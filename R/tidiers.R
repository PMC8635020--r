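# broom-style tidiers and ggplot2 autoplot methods for the result objects.

#' @rdname tidy.lognormal_fit
#' @export
glance.lognormal_fit <- function(x, ...) {
  tibble::tibble(mu = x$mu, sigma = x$sigma, mode = x$mode,
                 std_dev = x$std_dev, statistic = x$statistic,
                 p_value = x$p_value, n_used = x$n_used,
                 n_excluded = x$n_excluded)
}

#' Tidy a log-normal disarray fit
#'
#' `tidy()` returns one row per parameter; `glance()` a one-row summary with
#' the derived mode/SD and the log-normality test.
#'
#' @param x a [fit_lognormal()] object.
#' @param ... unused.
#' @return a tibble.
#' @export
tidy.lognormal_fit <- function(x, ...) {
  tibble::tibble(term = c("mu", "sigma", "mode", "std_dev"),
                 estimate = c(x$mu, x$sigma, x$mode, x$std_dev))
}

#' @rdname tidy.disarray_map
#' @export
glance.disarray_map <- function(x, ...) {
  tibble::tibble(m = attr(x, "m"), side_um = attr(x, "side_um"),
                 N_v = attr(x, "N_v"), D = attr(x, "D"), A = attr(x, "A"))
}

#' Tidy a disarray map
#'
#' `tidy()` returns the valid macrovoxels; `glance()` the global summary
#' (scale, valid count, global disarray and alignment).
#'
#' @param x a [disarray_map()].
#' @param ... unused.
#' @return a tibble.
#' @export
tidy.disarray_map <- function(x, ...) {
  tibble::as_tibble(x)[x$valid,
                       c("gz", "gy", "gx", "zc_um", "yc_um", "xc_um",
                         "n_reliable", "d", "a")]
}

#' @rdname tidy.validation_report
#' @export
glance.validation_report <- function(x, ...) {
  e <- attr(x, "errors")
  in20 <- abs(e$theta) <= 20
  tibble::tibble(
    mean_abs_dphi = mean(abs(e$dphi), na.rm = TRUE),
    mean_abs_dtheta = mean(abs(e$dtheta), na.rm = TRUE),
    mean_abs_dtheta_within_20 = mean(abs(e$dtheta[in20]), na.rm = TRUE),
    bias_dphi = mean(e$dphi, na.rm = TRUE),
    bias_dtheta = mean(e$dtheta[in20], na.rm = TRUE),
    n = sum(!is.na(e$dtheta))
  )
}

#' Tidy a rotation-validation report
#'
#' `tidy()` returns the pooled per-chunk errors; `glance()` the pooled mean
#' absolute errors (azimuth over the full grid, elevation restricted to the
#' resolvable `|theta| <= 20` degrees) and biases.
#'
#' @param x a [run_validation()] report.
#' @param ... unused.
#' @return a tibble.
#' @export
tidy.validation_report <- function(x, ...) {
  tibble::as_tibble(attr(x, "errors"))
}

#' Heatmaps of angle-recovery error
#'
#' @param object a [run_validation()] report.
#' @param which `"theta"` or `"phi"`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.validation_report <- function(object, which = c("theta", "phi"), ...) {
  which <- match.arg(which)
  col <- if (which == "theta") "mean_abs_dtheta" else "mean_abs_dphi"
  ggplot2::ggplot(object, ggplot2::aes(.data$phi, .data$theta,
                                       fill = .data[[col]])) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = sprintf("|d%s| (deg)", which)) +
    ggplot2::labs(x = "applied azimuth (deg)", y = "applied elevation (deg)",
                  title = sprintf("Mean absolute %s recovery error", which)) +
    ggplot2::coord_equal()
}

#' Mid-plane slice of a disarray map
#'
#' @param object a [disarray_map()].
#' @param gz macrovoxel Z slice to show (default: middle).
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.disarray_map <- function(object, gz = NULL, ...) {
  gz <- gz %||% ceiling(max(object$gz) / 2)
  df <- tibble::as_tibble(object)[object$gz == gz & object$valid, ]
  ggplot2::ggplot(df, ggplot2::aes(.data$xc_um, .data$yc_um, fill = .data$d)) +
    ggplot2::geom_tile(width = attr(object, "side_um"),
                       height = attr(object, "side_um")) +
    ggplot2::scale_fill_viridis_c(name = "disarray (%)") +
    ggplot2::labs(x = "x (um)", y = "y (um)",
                  title = sprintf("Local disarray, %g um macrovoxels (slice %d)",
                                  attr(object, "side_um"), gz)) +
    ggplot2::coord_equal()
}

#' Fitted log-normal disarray PDF
#'
#' @param object a [fit_lognormal()].
#' @param d_max upper disarray bound of the plotted grid (%), default 50.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.lognormal_fit <- function(object, d_max = 50, ...) {
  stopifnot(is.finite(object$mu))
  grid <- seq(0.01, d_max, length.out = 400)
  df <- tibble::tibble(d = grid, pdf = dlnorm(grid, object$mu, object$sigma))
  ggplot2::ggplot(df, ggplot2::aes(.data$d, .data$pdf)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$mode, linetype = 2) +
    ggplot2::labs(x = "local disarray (%)", y = "density",
                  title = sprintf("Log-normal LDD fit (mode %.2f%%)", object$mode))
}

#' In-plane quiver of a vector field
#'
#' Draws the XY projection of the reliable orientation vectors of one chunk
#' plane, coloured by alignment with the traction axis.
#'
#' @param field a `vector_field`.
#' @param iz chunk plane (default: middle).
#' @param scale arrow length in micrometres, default half a chunk.
#' @return a ggplot.
#' @export
plot_vector_field <- function(field, iz = NULL, scale = NULL) {
  stopifnot(inherits(field, "vector_field"))
  iz <- iz %||% ceiling(max(field$iz) / 2)
  scale <- scale %||% (attr(field, "chunk_um") / 2)
  df <- tibble::as_tibble(field)[field$iz == iz & field$is_reliable, ]
  ggplot2::ggplot(df) +
    ggplot2::geom_segment(ggplot2::aes(
      x = .data$xc_um - scale * .data$vx, xend = .data$xc_um + scale * .data$vx,
      y = .data$yc_um - scale * .data$vy, yend = .data$yc_um + scale * .data$vy,
      colour = .data$vy)) +
    ggplot2::scale_colour_viridis_c(name = "alignment (vy)", limits = c(0, 1)) +
    ggplot2::labs(x = "x (um)", y = "y (um)",
                  title = sprintf("Orientation field, chunk plane %d", iz)) +
    ggplot2::coord_equal()
}
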