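#' Load a grayscale image from PNG or TIFF
#'
#' Images are returned as an integer matrix of 8-bit intensities (rows = y,
#' columns = x, origin top-left). Color inputs are converted to grayscale by
#' ITU-R BT.601 luminance (0.299 R + 0.587 G + 0.114 B). 16-bit inputs are
#' rescaled to 8 bits by a linear min-max mapping (with a warning), so that
#' downstream thresholds always act on the \[0, 255\] range.
#'
#' @param path Path to a `.png`, `.tif` or `.tiff` file.
#' @return An integer matrix with values in \[0, 255\].
#' @export
load_image <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("image file not found: ", path), class = "poremorph_io")
  }
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    abort(paste0("unsupported image format: .", ext, " (use PNG or TIFF)"),
          class = "poremorph_format")
  )
  if (length(dim(arr)) == 3) {
    nc <- dim(arr)[3]
    if (nc >= 3) {
      arr <- 0.299 * arr[, , 1] + 0.587 * arr[, , 2] + 0.114 * arr[, , 3]
    } else {
      arr <- arr[, , 1]
    }
  }
  # readPNG/readTIFF scale to [0,1]; 16-bit data shows as finer quantization.
  # Map to 0..255; if the source was 16-bit, min-max rescale and warn.
  v <- arr * 255
  if (any(abs(v - round(v)) > 1e-6)) {
    rng <- range(arr)
    if (diff(rng) > 0) arr <- (arr - rng[1]) / diff(rng)
    warn("high-bit-depth input rescaled to 8-bit by linear min-max mapping")
    v <- arr * 255
  }
  img <- matrix(as.integer(round(v)), nrow(arr), ncol(arr))
  img[img < 0L] <- 0L
  img[img > 255L] <- 255L
  img
}

#' Write an image losslessly as PNG
#'
#' Accepts an 8-bit grayscale matrix or an H x W x 3 RGB array (values in
#' \[0, 255\]); a save/load round trip preserves pixels exactly.
#'
#' @param image Matrix or 3-d array of intensities in \[0, 255\].
#' @param path Output path ending in `.png`.
#' @return The path, invisibly.
#' @export
save_png <- function(image, path) {
  if (tolower(tools::file_ext(path)) != "png") {
    abort("save_png writes PNG files only", class = "poremorph_format")
  }
  png::writePNG(image / 255, target = path)
  invisible(path)
}

# validate an in-memory grayscale image
check_gray_image <- function(img) {
  if (!is.matrix(img) || !is.numeric(img) || nrow(img) < 1 || ncol(img) < 1)
    abort("image must be a nonempty numeric matrix", class = "poremorph_contract")
  if (any(img < 0 | img > 255))
    abort("image intensities must lie in [0, 255]", class = "poremorph_contract")
  invisible(img)
}
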