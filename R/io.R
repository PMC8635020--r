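#' Read an image volume from TIFF
#'
#' Accepts either a multi-page TIFF stack or a directory of single-plane
#' TIFFs (stacked in filename sort order). 8/16-bit integer data are kept on
#' their native integer scale; float TIFFs are read as-is.
#'
#' @param path TIFF file or directory of per-plane TIFFs.
#' @param voxel voxel size `(dz, dy, dx)` in micrometres.
#' @return A [volume()].
#' @export
read_volume <- function(path, voxel = c(2, 0.44, 0.44)) {
  if (!file.exists(path)) stop("no such file or directory: ", path)
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.tiff?$", ignore.case = TRUE,
                             full.names = TRUE))
    if (!length(files)) stop("no TIFF files in directory: ", path)
    planes <- unlist(lapply(files, read_tiff_planes), recursive = FALSE)
  } else {
    planes <- read_tiff_planes(path)
  }
  shp <- vapply(planes, dim, integer(2))
  if (any(shp[1, ] != shp[1, 1]) || any(shp[2, ] != shp[2, 1])) {
    stop("inconsistent plane shapes across TIFF pages")
  }
  a <- array(0, c(length(planes), shp[1, 1], shp[2, 1]))
  for (z in seq_along(planes)) a[z, , ] <- planes[[z]]
  volume(a, voxel)
}

read_tiff_planes <- function(file) {
  pl <- tiff::readTIFF(file, all = TRUE, info = TRUE)
  lapply(pl, function(p) {
    bits <- attr(p, "bits.per.sample") %||% 8L
    if (length(dim(p)) == 3L) p <- p[, , 1]  # drop extra channels
    p <- unname(p)
    attributes(p)[setdiff(names(attributes(p)), "dim")] <- NULL
    # integer pages come back as value/(2^bits - 1); float pages store
    # value/255 (see write_volume). Both land on the 0-255 scale:
    p * switch(as.character(bits), "8" = 255, "16" = 65535, 255)
  })
}

#' Write an image volume to a multi-page TIFF
#'
#' Intensities live on the 8-bit scale `[0, 255]` at every pipeline stage;
#' integer-valued volumes are written as 8-bit, fractional ones (e.g.
#' rendered disarray maps, in percent) as 32-bit float storing `value / 255`.
#'
#' @param v a [volume()] (a [mask_volume()] is written as 0/255 8-bit).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_volume <- function(v, path) {
  stopifnot(inherits(v, "volume"))
  a <- v$data
  if (is.logical(a)) a <- a * 255
  if (min(a) < 0 || max(a) > 255) {
    stop("volume intensities must lie in [0, 255] for TIFF export")
  }
  nz <- dim(a)[1]
  int8 <- all(a == round(a))
  planes <- lapply(seq_len(nz), function(z) a[z, , ] / 255)
  ok <- tiff::writeTIFF(planes, path,
                        bits.per.sample = if (int8) 8L else 32L)
  if (!ok) stop("failed to write TIFF: ", path)
  invisible(path)
}

#' Persist a vector field as a TSV table
#'
#' One row per chunk: grid indices, centre coordinates in micrometres, the
#' orientation vector `(vx, vy, vz)`, its spatial frequency and sarcomere
#' period, the raw and normalized Sratio, tissue fraction and the
#' tissue/reliable/outlier flags. Grid metadata travel in `#`-prefixed header
#' comments so [read_vector_field()] restores a working field.
#'
#' @param field a `vector_field` tibble from [analyze_volume()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_vector_field <- function(field, path) {
  stopifnot(inherits(field, "vector_field"))
  hdr <- c(
    paste0("# grid_dim = ", paste(attr(field, "grid_dim"), collapse = ",")),
    paste0("# chunk_um = ", format(attr(field, "chunk_um"), digits = 10)),
    paste0("# voxel = ", paste(format(attr(field, "voxel"), digits = 10), collapse = ","))
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  df <- as.data.frame(field)
  num <- vapply(df, is.double, TRUE)
  df[num] <- lapply(df[num], function(x) signif(x, 7))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Read back a vector field written by [write_vector_field()]
#'
#' @param path TSV path.
#' @return A `vector_field` tibble.
#' @export
read_vector_field <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path, n = 10)
  hdr <- lines[startsWith(lines, "#")]
  meta <- function(key) {
    ln <- hdr[grepl(paste0("^#\\s*", key, "\\s*="), hdr)]
    as.numeric(strsplit(sub("^[^=]*=", "", ln[1]), ",")[[1]])
  }
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE)
  tb <- tibble::as_tibble(df)
  for (fl in c("is_tissue", "is_reliable", "is_outlier")) {
    tb[[fl]] <- as.logical(tb[[fl]])
  }
  new_vector_field(tb,
                   grid_dim = as.integer(meta("grid_dim")),
                   chunk_um = meta("chunk_um"),
                   voxel = meta("voxel"))
}

new_vector_field <- function(tb, grid_dim, chunk_um, voxel) {
  structure(tb,
            grid_dim = grid_dim, chunk_um = chunk_um, voxel = voxel,
            class = c("vector_field", class(tibble::as_tibble(tb))))
}

#' @export
print.vector_field <- function(x, ...) {
  gd <- attr(x, "grid_dim")
  cat(sprintf("<vector_field> grid %s chunks (%g um); %d tissue, %d reliable of %d\n",
              paste(gd, collapse = " x "), attr(x, "chunk_um"),
              sum(x$is_tissue), sum(x$is_reliable), nrow(x)))
  NextMethod()
}
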