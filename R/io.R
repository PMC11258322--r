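# Optional raster export for visual inspection.

#' Export structural amplitude or a strain map as TIFF
#'
#' Writes the central B-scan (or a chosen one) of a volume's amplitude, or of
#' a strain/displacement field, as a normalised grayscale TIFF for quick
#' inspection. Requires the optional `tiff` package.
#'
#' @param x An [oce_volume()] (amplitude is written) or an `oce_field`
#'   (invalid pixels are written as 0).
#' @param path Output file path.
#' @param y_index B-scan index (default central).
#' @return `path`, invisibly.
#' @export
export_tiff <- function(x, path, y_index = NULL) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the 'tiff' package is required for TIFF export", call. = FALSE)
  img <- if (inherits(x, "oce_volume")) {
    Mod(x$data)
  } else if (inherits(x, "oce_field")) {
    m <- x$data
    m[!x$valid] <- 0
    m
  } else {
    stop("'x' must be an 'oce_volume' or an 'oce_field'", call. = FALSE)
  }
  y <- y_index %||% as.integer(ceiling(dim(img)[3] / 2))
  sl <- img[, , y]
  rng <- range(sl)
  sl <- if (diff(rng) > 0) (sl - rng[1]) / diff(rng) else sl * 0
  tiff::writeTIFF(sl, path)
  invisible(path)
}
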