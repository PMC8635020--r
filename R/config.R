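#' Pipeline run configuration
#'
#' Collects every tunable parameter of the orientation/disarray pipeline
#' with the defaults used throughout: these defaults reproduce a complete
#' analysis of a two-photon Z-band stack without further tuning.
#'
#' @param clip_limit CLAHE normalized clip limit (fraction of tile area a
#'   histogram bin may hold), default 0.08.
#' @param k_clusters number of K-means intensity clusters for segmentation,
#'   default 4.
#' @param chunk_um side of the cubic analysis chunk in micrometres,
#'   default 16.
#' @param tissue_fraction_min minimum in-mask fraction for a chunk to be
#'   analysed, default 0.80.
#' @param period_range_um admissible sarcomere period band `(min, max)` in
#'   micrometres, default `c(1.6, 2.0)`.
#' @param sratio_threshold reliability threshold on the min-max normalized
#'   Sratio, default 0.14.
#' @param macrovoxel_m_list macrovoxel sides, in orientation vectors, for the
#'   multi-scale disarray analysis; default `2:6` (32-96 um at 16 um chunks).
#' @param map_smooth_sigma_um Gaussian sigma for rendered disarray maps, in
#'   micrometres, default 10.
#' @param seed integer seed for all stochastic steps.
#'
#' @return A list of class `run_config`.
#' @export
#'
#' @examples
#' cfg <- run_config(seed = 7)
#' cfg$chunk_um
run_config <- function(clip_limit = 0.08,
                       k_clusters = 4L,
                       chunk_um = 16,
                       tissue_fraction_min = 0.80,
                       period_range_um = c(1.6, 2.0),
                       sratio_threshold = 0.14,
                       macrovoxel_m_list = 2:6,
                       map_smooth_sigma_um = 10,
                       seed = 1L) {
  stopifnot(
    clip_limit > 0, clip_limit < 1,
    k_clusters >= 2,
    chunk_um > 0,
    tissue_fraction_min > 0, tissue_fraction_min < 1,
    length(period_range_um) == 2, period_range_um[1] < period_range_um[2],
    sratio_threshold > 0, sratio_threshold < 1,
    all(macrovoxel_m_list >= 2),
    map_smooth_sigma_um >= 0
  )
  structure(list(
    clip_limit = clip_limit,
    k_clusters = as.integer(k_clusters),
    chunk_um = chunk_um,
    tissue_fraction_min = tissue_fraction_min,
    period_range_um = period_range_um,
    sratio_threshold = sratio_threshold,
    macrovoxel_m_list = as.integer(macrovoxel_m_list),
    map_smooth_sigma_um = map_smooth_sigma_um,
    seed = as.integer(seed)
  ), class = "run_config")
}

#' Read / write a run configuration as flat key = value text
#'
#' Vector-valued keys are comma-separated. Unknown keys are an error so typos
#' in config files fail loudly.
#'
#' @param path file path.
#' @param config a [run_config()].
#' @return `read_config()` returns a [run_config()]; `write_config()` returns
#'   `path` invisibly.
#' @export
read_config <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(kv) != 2
  if (any(bad)) stop("malformed config line(s): ", paste(lines[bad], collapse = "; "))
  keys <- trimws(vapply(kv, `[`, "", 1))
  vals <- trimws(vapply(kv, `[`, "", 2))
  known <- names(formals(run_config))
  unknown <- setdiff(keys, known)
  if (length(unknown)) stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  args <- lapply(vals, function(v) as.numeric(strsplit(v, ",", fixed = TRUE)[[1]]))
  names(args) <- keys
  do.call(run_config, args)
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  lines <- vapply(names(config), function(k) {
    paste0(k, " = ", paste(format(config[[k]], digits = 10), collapse = ","))
  }, "")
  writeLines(lines, path)
  invisible(path)
}
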