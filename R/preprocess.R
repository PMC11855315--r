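#' Contrast-limited adaptive histogram equalization
#'
#' Splits the image into tiles, equalizes each tile's histogram with the
#' excess above the clip limit redistributed, and blends the tile mappings
#' bilinearly. On SEM cross sections that are not level, darkness varies with
#' depth across the frame; CLAHE flattens that illumination so the global
#' threshold acts uniformly: lighter regions are darkened and darker regions
#' lightened.
#'
#' Images whose sides are not multiples of the tile grid are padded by edge
#' replication before equalization and cropped back afterwards.
#'
#' @param img 8-bit grayscale matrix.
#' @param clahe_size Kernel size parameter (>= 1). With `units = "tiles"` the
#'   image is split into `clahe_size x clahe_size` tiles; with
#'   `units = "pixels"` tiles are approximately `clahe_size` pixels on a side.
#' @param clip_limit Contrast clip limit (> 0), as a multiple of the uniform
#'   histogram level.
#' @param units Interpretation of `clahe_size` (see above).
#' @return An 8-bit grayscale matrix of the same dimensions.
#' @export
apply_clahe <- function(img, clahe_size = 8, clip_limit = 2,
                        units = c("tiles", "pixels")) {
  check_gray_image(img)
  units <- match.arg(units)
  if (clahe_size < 1)
    abort("clahe_size must be >= 1", class = "poremorph_contract")
  h <- nrow(img); w <- ncol(img)
  if (clahe_size > min(h, w))
    abort("clahe_size exceeds the image side: tiles would be degenerate",
          class = "poremorph_degenerate_tile")
  if (units == "tiles") {
    nx <- as.integer(clahe_size); ny <- as.integer(clahe_size)
  } else {
    nx <- max(1L, as.integer(round(w / clahe_size)))
    ny <- max(1L, as.integer(round(h / clahe_size)))
  }
  if (nx < 2 || ny < 2) {
    # single-tile degenerate grid: global clipped histogram equalization
    # (no tile interpolation needed)
    return(clipped_hist_eq(img, clip_limit))
  }
  # pad by edge replication to a multiple of the tile grid (EBImage requires it)
  ph <- ceiling(h / ny) * ny
  pw <- ceiling(w / nx) * nx
  pad_rows <- ph - h; pad_cols <- pw - w
  m <- img
  if (pad_rows > 0) m <- rbind(m, m[rep(h, pad_rows), , drop = FALSE])
  if (pad_cols > 0) m <- cbind(m, m[, rep(w, pad_cols), drop = FALSE])
  # EBImage stores images x-first
  eq <- EBImage::clahe(t(m) / 255, nx = nx, ny = ny, limit = clip_limit)
  out <- t(as.matrix(eq))[seq_len(h), seq_len(w), drop = FALSE]
  out <- matrix(as.integer(pmin(pmax(round(out * 255), 0), 255)), h, w)
  out
}

# Global clipped histogram equalization: histogram counts above
# clip_limit * uniform level are clipped, the excess is redistributed
# uniformly, and intensities map through the scaled CDF (so an unbounded clip
# limit reduces to classic histogram equalization).
clipped_hist_eq <- function(img, clip_limit) {
  n <- length(img)
  counts <- tabulate(as.integer(img) + 1L, nbins = 256)
  beta <- clip_limit * n / 256
  excess <- sum(pmax(counts - beta, 0))
  clipped <- pmin(counts, beta) + excess / 256
  cdf <- cumsum(clipped) / n
  map <- as.integer(pmin(pmax(round(255 * cdf), 0), 255))
  matrix(map[as.integer(img) + 1L], nrow(img), ncol(img))
}

#' Non-local-means denoising
#'
#' Fast non-local means (Buades et al.): each pixel is replaced by a weighted
#' mean of pixels in a 21 x 21 search window whose patch neighborhoods look
#' similar, with weights `exp(-d2 / strength^2)` decaying in the mean squared
#' patch difference `d2`. Removes stray pixels and speckle that would
#' otherwise be traced as spurious contours, while preserving pore edges.
#' Note that smoothing contour edges can markedly change the isoperimetric
#' ratio of a pore without changing its area.
#'
#' @param img 8-bit grayscale matrix.
#' @param strength Filter strength `h` (>= 0); 0 returns the image unchanged.
#' @param kernel_size Odd patch side in pixels (>= 3).
#' @return An 8-bit grayscale matrix of the same dimensions.
#' @export
denoise_nlm <- function(img, strength = 30, kernel_size = 7) {
  check_gray_image(img)
  if (strength < 0) abort("strength must be >= 0", class = "poremorph_contract")
  if (kernel_size < 3 || kernel_size %% 2 == 0)
    abort("kernel_size must be odd and >= 3", class = "poremorph_contract")
  if (strength == 0) return(matrix(as.integer(round(img)), nrow(img), ncol(img)))
  out <- .nlm_denoise_cpp(img + 0.0, strength, as.integer(kernel_size), 21L)
  matrix(as.integer(pmin(pmax(round(out), 0), 255)), nrow(img), ncol(img))
}

#' Binary cutoff thresholding
#'
#' Pixels with intensity strictly under the cutoff turn black (pore
#' candidates); pixels at or over it turn white. Raising the cutoff turns
#' lighter pixels black, which typically "erodes" pore edges outward.
#'
#' @param img 8-bit grayscale matrix.
#' @param cutoff Threshold in \[0, 255\].
#' @return A `binary_image`: logical matrix, `TRUE` = black (pore candidate).
#' @export
apply_threshold <- function(img, cutoff) {
  check_gray_image(img)
  if (cutoff < 0 || cutoff > 255)
    abort("cutoff must lie in [0, 255]", class = "poremorph_contract")
  structure(img < cutoff, class = c("binary_image", "matrix"),
            cutoff = cutoff)
}

#' Run the full preprocessing chain
#'
#' Fixed order: CLAHE, then non-local-means denoising, then cutoff
#' thresholding. Intermediate images are returned so they can be used as
#' overlay underlays or inspected when tuning settings.
#'
#' @param img 8-bit grayscale matrix.
#' @param settings A [pore_settings()] bundle.
#' @return List with `clahe`, `denoised` (grayscale matrices) and `binary`
#'   (the thresholded `binary_image`).
#' @export
preprocess_image <- function(img, settings) {
  stopifnot(inherits(settings, "pore_settings"))
  cl <- if (settings$clahe_size >= 1) {
    apply_clahe(img, settings$clahe_size, settings$clahe_clip_limit,
                settings$clahe_units)
  } else {
    matrix(as.integer(round(img)), nrow(img), ncol(img))
  }
  dn <- denoise_nlm(cl, settings$denoise_strength, settings$denoise_size)
  bin <- apply_threshold(dn, settings$grayscale_threshold)
  list(clahe = cl, denoised = dn, binary = bin)
}
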