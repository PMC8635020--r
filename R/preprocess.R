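# Per-plane equalization and tissue segmentation. Z-band staining gives a
# sparse, periodic signal whose brightness drifts with depth; CLAHE evens it
# out frame by frame before an intensity-based K-means segmentation labels
# contractile tissue.

#' Contrast-limited adaptive histogram equalization of one frame
#'
#' Applies CLAHE per Z-plane and rescales the result to the full 8-bit range.
#' The tile grid targets ~128 px tiles (8 x 8 on a 1024 x 1024 frame) and the
#' frame is edge-replicated to a tile multiple before equalization, then
#' cropped back.
#'
#' @param frame numeric matrix (one Z-plane), any intensity scale.
#' @param clip_limit normalized clip limit in (0, 1): the fraction of a
#'   tile's pixels a single histogram bin may hold. 0.08 gives the strong
#'   equalization the Z-band signal needs.
#' @return numeric matrix, same shape, values in `[0, 255]`.
#' @export
equalize_frame <- function(frame, clip_limit = 0.08) {
  stopifnot(is.matrix(frame), clip_limit > 0, clip_limit < 1)
  rng <- range(frame)
  if (rng[1] == rng[2]) return(frame)  # constant frame: nothing to equalize
  x <- (frame - rng[1]) / (rng[2] - rng[1])
  d <- dim(x)
  ntile <- pmax(2L, pmin(8L, round(d / 128)))
  pad <- (ntile - d %% ntile) %% ntile
  if (any(pad > 0)) {
    x <- x[c(seq_len(d[1]), rep(d[1], pad[1])),
           c(seq_len(d[2]), rep(d[2], pad[2]))]
  }
  eq <- EBImage::clahe(x, nx = ntile[1], ny = ntile[2], bins = 256L,
                       limit = clip_limit * 256, keep.range = FALSE)
  eq <- eq[seq_len(d[1]), seq_len(d[2])]
  eq <- eq - min(eq)
  if (max(eq) > 0) eq <- eq / max(eq)
  eq * 255
}

#' Segment one equalized frame into Background and Tissue
#'
#' The frame is lightly denoised (Gaussian, `denoise_sigma` px) so that
#' noise amplified by the equalization averages to mid-grey while coherent
#' Z-band structure stays bright; pixel intensities are then quantized into
#' `k_clusters` balanced clusters with K-means (deterministic quantile
#' initialization), clusters are sorted by mean intensity, and a second,
#' dynamic classification assigns labels: the cluster sequence is split at
#' the largest gap between consecutive centres, darker clusters becoming
#' Background and brighter ones Tissue — so the same rule handles frames
#' with very different tissue quantity. Frames whose cluster centres span
#' less than 10% of the intensity range are treated as tissue-free. Frames
#' with fewer distinct values than clusters fall back to a single Otsu
#' threshold.
#'
#' @param frame equalized numeric matrix (values in `[0, 255]`).
#' @param k_clusters number of intensity clusters, default 4.
#' @param denoise_sigma pre-clustering Gaussian sigma in px; 0 disables.
#' @return logical matrix, `TRUE` = Tissue.
#' @export
segment_frame <- function(frame, k_clusters = 4L, denoise_sigma = 1) {
  stopifnot(is.matrix(frame), k_clusters >= 2)
  if (denoise_sigma > 0 && min(dim(frame)) > 4 * denoise_sigma) {
    frame <- 255 * EBImage::gblur(frame / 255, denoise_sigma)
  }
  x <- as.vector(frame)
  centers <- segment_centers(x, k_clusters)
  if (is.null(centers)) {  # degenerate frame: Otsu-style split
    lab <- otsu_split(frame)
    return(lab)
  }
  km <- centers$km
  ord <- order(km$centers[, 1])
  means <- km$centers[ord, 1]
  if (diff(range(means)) < 0.10 * 255) {
    return(matrix(FALSE, nrow(frame), ncol(frame)))  # low contrast: no tissue
  }
  n_bg <- which.max(diff(means))  # split at the largest centre gap
  bg_clusters <- ord[seq_len(n_bg)]
  matrix(!(km$cluster %in% bg_clusters), nrow(frame), ncol(frame))
}

segment_centers <- function(x, k) {
  if (length(unique(x)) < k) return(NULL)
  init <- quantile(x, probs = (2 * seq_len(k) - 1) / (2 * k), names = FALSE)
  if (anyDuplicated(init)) return(NULL)
  km <- tryCatch(
    kmeans(x, centers = matrix(init, ncol = 1), iter.max = 50L),
    error = function(e) NULL
  )
  if (is.null(km)) NULL else list(km = km)
}

otsu_split <- function(frame) {
  rng <- range(frame)
  if (rng[1] == rng[2]) return(matrix(FALSE, nrow(frame), ncol(frame)))
  x <- (frame - rng[1]) / (rng[2] - rng[1])
  thr <- EBImage::otsu(EBImage::Image(x), range = c(0, 1))
  message("segment_frame: < k distinct intensities, using Otsu threshold")
  matrix(x > thr, nrow(frame), ncol(frame))
}

#' Morphological cleanup of a binary mask
#'
#' Closing then opening with a disk (radius 2 px) bridges the ~4 px gaps
#' between Z-bands into solid cell footprints without merging distinct cells,
#' then specks under `min_size` px are dropped and holes up to `max_hole` px
#' filled. 3D masks are refined plane by plane.
#'
#' @param mask logical matrix or 3D array (or a [mask_volume()]).
#' @param radius_px structuring-disk radius, default 2.
#' @param min_size minimum connected-component area kept, default 100 px.
#' @param max_hole largest hole area filled, default 100 px.
#' @return same type as the input, still strictly binary.
#' @export
refine_mask <- function(mask, radius_px = 2L, min_size = 100L, max_hole = 100L) {
  if (inherits(mask, "mask")) {
    return(mask_volume(refine_mask(mask$data, radius_px, min_size, max_hole),
                       mask$voxel))
  }
  if (is.array(mask) && length(dim(mask)) == 3L) {
    out <- mask
    for (z in seq_len(dim(mask)[1])) {
      out[z, , ] <- refine_mask(mask[z, , ], radius_px, min_size, max_hole)
    }
    return(out)
  }
  stopifnot(is.matrix(mask))
  m <- matrix(as.numeric(mask > 0), nrow(mask), ncol(mask))
  if (!any(m > 0)) return(matrix(FALSE, nrow(mask), ncol(mask)))
  brush <- EBImage::makeBrush(2L * radius_px + 1L, shape = "disc")
  m <- EBImage::opening(EBImage::closing(m, brush), brush)
  lab <- EBImage::bwlabel(m)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_size)
  m <- matrix(lab %in% keep, nrow(mask), ncol(mask))
  fill_small_holes(m, max_hole)
}

# Fill background components that touch no border and are <= max_hole px.
fill_small_holes <- function(m, max_hole) {
  bg <- EBImage::bwlabel(matrix(as.numeric(!m), nrow(m), ncol(m)))
  if (max(bg) == 0) return(m)
  border_ids <- unique(c(bg[1, ], bg[nrow(bg), ], bg[, 1], bg[, ncol(bg)]))
  sizes <- tabulate(bg[bg > 0])
  fill <- setdiff(which(sizes <= max_hole), border_ids)
  m | matrix(bg %in% fill, nrow(m), ncol(m))
}

#' Equalize and segment a whole volume
#'
#' Runs [equalize_frame()], [segment_frame()] and [refine_mask()] on every
#' Z-plane, stacks the masks to 3D and crops the equalized volume with the
#' mask (outside-mask voxels set to 0). Planes whose raw dynamic range
#' (1st-99th percentile) is below 10% of the 8-bit range carry no tissue
#' signal — equalizing them would only amplify noise — and get an empty mask.
#'
#' @param v a [volume()].
#' @param config a [run_config()].
#' @return list with elements `equalized` ([volume()]), `mask`
#'   ([mask_volume()]) and `masked` ([volume()]).
#' @export
preprocess_volume <- function(v, config = run_config()) {
  stopifnot(inherits(v, "volume"))
  d <- dim(v$data)
  eq <- array(0, d)
  mk <- array(FALSE, d)
  for (z in seq_len(d[1])) {
    qs <- quantile(v$data[z, , ], c(0.01, 0.99), names = FALSE)
    if (qs[2] - qs[1] < 0.10 * 255) {
      eq[z, , ] <- v$data[z, , ]  # background plane: keep raw, empty mask
      next
    }
    fr <- tryCatch(equalize_frame(v$data[z, , ], config$clip_limit),
                   error = function(e) stop("plane ", z, ": ", conditionMessage(e)))
    sg <- tryCatch(segment_frame(fr, config$k_clusters),
                   error = function(e) stop("plane ", z, ": ", conditionMessage(e)))
    eq[z, , ] <- fr
    mk[z, , ] <- refine_mask(sg)
  }
  masked <- eq
  masked[!mk] <- 0
  list(equalized = volume(eq, v$voxel),
       mask = mask_volume(mk, v$voxel),
       masked = volume(masked, v$voxel))
}
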