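#' Define the spatial scale of an analysis
#'
#' SEM micrographs carry a scalebar in an information band. After cropping the
#' band away, the user measures the scalebar length in pixels and supplies it
#' together with its micrometer reading; all measurements are then converted
#' from pixels with the factor `um_per_px = scalebar_reading_um /
#' scalebar_length_px`. In `"pixel"` mode no conversion is applied and all
#' outputs stay in pixel units.
#'
#' @param mode `"pixel"` (no unit conversion) or `"supplied"` (scalebar given).
#' @param scalebar_length_px Length of the scalebar in pixels (supplied mode).
#' @param scalebar_reading_um Scalebar reading in micrometers (supplied mode).
#' @return A `scale_spec` object with the derived `um_per_px` factor.
#' @examples
#' make_scale("supplied", scalebar_length_px = 200, scalebar_reading_um = 100)
#' make_scale("pixel")
#' @export
make_scale <- function(mode = c("pixel", "supplied"),
                       scalebar_length_px = NULL,
                       scalebar_reading_um = NULL) {
  mode <- match.arg(mode)
  if (mode == "supplied") {
    if (is.null(scalebar_length_px) || is.null(scalebar_reading_um) ||
        !is.finite(scalebar_length_px) || !is.finite(scalebar_reading_um) ||
        scalebar_length_px <= 0 || scalebar_reading_um <= 0) {
      abort("supplied scale needs positive scalebar length (px) and reading (um)",
            class = "poremorph_invalid_scale")
    }
    um_per_px <- scalebar_reading_um / scalebar_length_px
  } else {
    scalebar_length_px <- NA_real_
    scalebar_reading_um <- NA_real_
    um_per_px <- 1
  }
  structure(
    list(mode = mode,
         scalebar_length_px = as.numeric(scalebar_length_px),
         scalebar_reading_um = as.numeric(scalebar_reading_um),
         um_per_px = um_per_px),
    class = "scale_spec"
  )
}

#' @export
print.scale_spec <- function(x, ...) {
  if (x$mode == "pixel") {
    cat("<scale_spec> pixel mode (no unit conversion)\n")
  } else {
    cat(sprintf("<scale_spec> supplied: %g px = %g um  (%g um/px)\n",
                x$scalebar_length_px, x$scalebar_reading_um, x$um_per_px))
  }
  invisible(x)
}

#' Convert a pixel-unit measurement to physical units
#'
#' Lengths scale with `um_per_px`, areas with its square, and inverse areas
#' (pore densities) are reported per square millimeter. In pixel mode the
#' value is returned unchanged.
#'
#' @param value Measurement in pixel units (px, px^2, or a count per px^2).
#' @param quantity One of `"length"`, `"area"`, `"inverse_area"`.
#' @param scale A [make_scale()] object.
#' @return The converted value: um, um^2, or counts per mm^2 (pixel mode: the
#'   input unchanged).
#' @examples
#' s <- make_scale("supplied", 200, 100)
#' convert_measurement(400, "area", s)   # 100 um^2
#' convert_measurement(40, "length", s)  # 20 um
#' @export
convert_measurement <- function(value, quantity = c("length", "area", "inverse_area"),
                                scale) {
  quantity <- match.arg(quantity)
  stopifnot(inherits(scale, "scale_spec"))
  if (quantity != "inverse_area" && any(is.finite(value) & value < 0)) {
    abort("lengths and areas must be nonnegative", class = "poremorph_contract")
  }
  if (scale$mode == "pixel") return(value)
  f <- scale$um_per_px
  switch(quantity,
         length = value * f,
         area = value * f^2,
         # counts per px^2 -> counts per mm^2: 1 mm^2 = (1000/f)^2 px^2
         inverse_area = value * (1000 / f)^2)
}

#' Analysis settings for one pass
#'
#' The six tunable parameters of a pass plus the scale specification. One
#' settings bundle is the "save profile" attached to every pore kept from
#' that pass.
#'
#' @param min_pore_size_px Minimum accepted contour area, px^2. Contours
#'   smaller than this are usually dust, cracks, or noise.
#' @param max_pore_size_px Maximum accepted contour area, px^2.
#' @param denoise_strength Non-local-means filter strength `h` (0 disables
#'   denoising).
#' @param denoise_size Odd patch side, in pixels, for non-local means.
#' @param grayscale_threshold Binary cutoff in \[0, 255\]: pixels strictly
#'   below turn black (pore candidates), the rest white.
#' @param clahe_size CLAHE kernel parameter (0 disables CLAHE). Interpreted
#'   per `clahe_units`.
#' @param clahe_clip_limit CLAHE contrast clip limit.
#' @param clahe_units `"tiles"`: `clahe_size` is the number of tiles per image
#'   side; `"pixels"`: it is the tile side in pixels.
#' @param scale A [make_scale()] object.
#' @return A `pore_settings` object.
#' @export
pore_settings <- function(min_pore_size_px = 100,
                          max_pore_size_px = 1e6,
                          denoise_strength = 30,
                          denoise_size = 7,
                          grayscale_threshold = 100,
                          clahe_size = 8,
                          clahe_clip_limit = 2,
                          clahe_units = c("tiles", "pixels"),
                          scale = make_scale("pixel")) {
  clahe_units <- match.arg(clahe_units)
  if (!is.finite(min_pore_size_px) || min_pore_size_px < 0)
    abort("min_pore_size_px must be >= 0", class = "poremorph_contract")
  if (!is.finite(max_pore_size_px) || max_pore_size_px <= min_pore_size_px)
    abort("max_pore_size_px must exceed min_pore_size_px", class = "poremorph_contract")
  if (denoise_strength < 0)
    abort("denoise_strength must be >= 0", class = "poremorph_contract")
  if (denoise_size < 1 || denoise_size %% 2 == 0)
    abort("denoise_size must be an odd positive integer", class = "poremorph_contract")
  if (grayscale_threshold < 0 || grayscale_threshold > 255)
    abort("grayscale_threshold must lie in [0, 255]", class = "poremorph_contract")
  if (clahe_size < 0)
    abort("clahe_size must be >= 0 (0 disables CLAHE)", class = "poremorph_contract")
  if (clahe_clip_limit <= 0)
    abort("clahe_clip_limit must be positive", class = "poremorph_contract")
  stopifnot(inherits(scale, "scale_spec"))
  structure(
    list(min_pore_size_px = min_pore_size_px,
         max_pore_size_px = max_pore_size_px,
         denoise_strength = denoise_strength,
         denoise_size = as.integer(denoise_size),
         grayscale_threshold = grayscale_threshold,
         clahe_size = as.integer(clahe_size),
         clahe_clip_limit = clahe_clip_limit,
         clahe_units = clahe_units,
         scale = scale),
    class = "pore_settings"
  )
}

#' @export
print.pore_settings <- function(x, ...) {
  cat("<pore_settings>\n")
  cat(sprintf("  size gates: [%g, %g] px^2\n", x$min_pore_size_px, x$max_pore_size_px))
  cat(sprintf("  denoise: strength %g, patch %d px\n", x$denoise_strength, x$denoise_size))
  cat(sprintf("  threshold: %g\n", x$grayscale_threshold))
  cat(sprintf("  CLAHE: size %d (%s), clip %g\n", x$clahe_size, x$clahe_units,
              x$clahe_clip_limit))
  print(x$scale)
  invisible(x)
}

#' Read analysis settings from a key=value config file
#'
#' Keys mirror the [pore_settings()] argument names exactly; `scale_mode`,
#' `scalebar_length_px` and `scalebar_reading_um` configure the scale. Blank
#' lines and `#` comments are ignored; unknown keys are an error.
#'
#' @param path Path to the config file.
#' @return A `pore_settings` object.
#' @export
read_settings <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(kv) != 2
  if (any(bad)) abort(paste0("malformed config line: ", lines[bad][1]),
                      class = "poremorph_contract")
  keys <- trimws(vapply(kv, `[`, "", 1))
  vals <- trimws(vapply(kv, `[`, "", 2))
  names(vals) <- keys
  known <- c("min_pore_size_px", "max_pore_size_px", "denoise_strength",
             "denoise_size", "grayscale_threshold", "clahe_size",
             "clahe_clip_limit", "clahe_units", "scale_mode",
             "scalebar_length_px", "scalebar_reading_um")
  unknown <- setdiff(keys, known)
  if (length(unknown))
    abort(paste0("unknown config key: ", unknown[1]), class = "poremorph_contract")
  num <- function(k, default) if (k %in% keys) as.numeric(vals[[k]]) else default
  mode <- if ("scale_mode" %in% keys) vals[["scale_mode"]] else "pixel"
  scale <- if (mode == "pixel") make_scale("pixel") else
    make_scale("supplied", num("scalebar_length_px", NA), num("scalebar_reading_um", NA))
  pore_settings(
    min_pore_size_px = num("min_pore_size_px", 100),
    max_pore_size_px = num("max_pore_size_px", 1e6),
    denoise_strength = num("denoise_strength", 30),
    denoise_size = num("denoise_size", 7),
    grayscale_threshold = num("grayscale_threshold", 100),
    clahe_size = num("clahe_size", 8),
    clahe_clip_limit = num("clahe_clip_limit", 2),
    clahe_units = if ("clahe_units" %in% keys) vals[["clahe_units"]] else "tiles",
    scale = scale
  )
}
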