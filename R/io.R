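#' Write / read a movie as 16-bit multi-page TIFF
#'
#' Intensities are scaled into the 16-bit range on write; the scale factor
#' and the frame timestamps are stored in a JSON sidecar (`<path>.json`)
#' and restored on read, so a round trip reproduces the movie up to 16-bit
#' quantization.
#'
#' @param movie a `ca_movie`.
#' @param path TIFF file path.
#' @return `read_movie_tiff` returns a `ca_movie`.
#' @export
write_movie_tiff <- function(movie, path) {
  stopifnot(inherits(movie, "ca_movie"))
  lo <- min(movie$frames); hi <- max(movie$frames)
  scale <- if (hi > lo) hi - lo else 1
  pages <- lapply(seq_len(n_frames(movie)), function(k) {
    (movie$frames[, , k] - lo) / scale
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16)
  jsonlite::write_json(list(times = movie$times, offset = lo, scale = scale),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_movie_tiff
#' @export
read_movie_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  frames <- array(0, dim = c(dim(pages[[1]]), length(pages)))
  for (k in seq_along(pages)) {
    frames[, , k] <- pages[[k]] * meta$scale + meta$offset
  }
  ca_movie(frames, meta$times)
}

#' Write / read an ROI label mask as 16-bit TIFF
#'
#' Integer labels (0 = background region) are stored in the 16-bit sample
#' directly.
#'
#' @param rois a [roi_set()] (or an integer matrix).
#' @param path TIFF file path.
#' @return `read_mask_tiff` returns the integer label matrix.
#' @export
write_mask_tiff <- function(rois, path) {
  mask <- if (inherits(rois, "roi_set")) rois$mask else rois
  tiff::writeTIFF(mask / 65535, path, bits.per.sample = 16)
  invisible(path)
}

#' @rdname write_mask_tiff
#' @export
read_mask_tiff <- function(path) {
  m <- tiff::readTIFF(path)
  matrix(as.integer(round(m * 65535)), nrow(m), ncol(m))
}

#' Write / read a movie-generator configuration as YAML
#'
#' @param config a [movie_config()].
#' @param path YAML file path.
#' @return `read_config_yaml` returns a `movie_config`.
#' @export
write_config_yaml <- function(config, path) {
  stopifnot(inherits(config, "movie_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config_yaml
#' @export
read_config_yaml <- function(path) {
  x <- yaml::read_yaml(path)
  do.call(movie_config, x)
}
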