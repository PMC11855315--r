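#' Specify a synthetic SEM phantom
#'
#' The phantom emulates an SEM micrograph of a porous cryogel cross section:
#' dark elliptical pores on a lighter matrix, an optional smooth linear
#' illumination gradient (as when the imaged cross section is not level), an
#' optional additive Gaussian noise floor or salt-and-pepper speckle, and an
#' optional information band with a drawn scalebar along the bottom edge.
#' Every planted pore is recorded in a ground-truth table so detection and
#' measurement can be scored exactly.
#'
#' Defaults emulate a 200x-magnification cryogel micrograph: 20 well-separated
#' pores with semi-minor axes of 10-16 px and aspect ratios 1.3-2.5 (cryogel
#' pores are moderately elongated; near-circular pores carry no recoverable
#' orientation), pore interiors at grey level 40 on a 200-level matrix.
#'
#' @param width,height Image size in px.
#' @param n_pores Number of interior pores to plant.
#' @param semi_minor_range,aspect_range Semi-minor axis (px) and major:minor
#'   aspect sampled uniformly; the semi-major axis is capped at
#'   `max_semi_major`.
#' @param max_semi_major Cap on the semi-major axis, px.
#' @param angle `"uniform"` or a fixed angle in degrees.
#' @param pore_intensity,background_intensity Grey levels in \[0, 255\];
#'   pores must be darker than the matrix.
#' @param illumination_gradient Half-amplitude of a horizontal linear ramp in
#'   grey levels: the ramp runs from `-g` at the left edge to `+g` at the
#'   right.
#' @param noise_sigma Standard deviation of i.i.d. additive Gaussian noise.
#' @param salt_pepper Fraction of pixels replaced by 0 or 255 speckle.
#' @param min_gap Minimum clearance in px between pore bounding circles and
#'   from the image border.
#' @param n_border_pores Pores planted straddling the image border (to
#'   exercise the border-rejection rule).
#' @param scalebar_band Optional `list(height_px=, bar_px=, reading_um=)`
#'   information band drawn along the bottom edge.
#' @param seed Integer seed; generation is fully deterministic given the spec.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(width = 1024, height = 1024, n_pores = 20,
                         semi_minor_range = c(10, 16),
                         aspect_range = c(1.3, 2.5),
                         max_semi_major = 40,
                         angle = "uniform",
                         pore_intensity = 40, background_intensity = 200,
                         illumination_gradient = 0, noise_sigma = 0,
                         salt_pepper = 0,
                         min_gap = 12, n_border_pores = 0,
                         scalebar_band = NULL, seed = 1) {
  if (pore_intensity >= background_intensity)
    abort("pores must be darker than the background matrix",
          class = "poremorph_contract")
  structure(list(width = width, height = height, n_pores = n_pores,
                 semi_minor_range = semi_minor_range,
                 aspect_range = aspect_range, max_semi_major = max_semi_major,
                 angle = angle, pore_intensity = pore_intensity,
                 background_intensity = background_intensity,
                 illumination_gradient = illumination_gradient,
                 noise_sigma = noise_sigma, salt_pepper = salt_pepper,
                 min_gap = min_gap, n_border_pores = n_border_pores,
                 scalebar_band = scalebar_band, seed = seed),
            class = "phantom_spec")
}

# Ramanujan's perimeter approximation for an ellipse with semi-axes a, b
ellipse_perimeter <- function(a, b) {
  pi * (3 * (a + b) - sqrt((3 * a + b) * (a + 3 * b)))
}

#' Generate a phantom image with exhaustive ground truth
#'
#' Pores are placed by rejection sampling with the requested clearance
#' (bounding-circle test); generation fails with an infeasible-spec error if
#' a placement cannot be found. The image is assembled as: background, filled
#' ellipses, illumination gradient, Gaussian noise, salt-and-pepper speckle,
#' then clipping to \[0, 255\] (gradient before noise, noise before clipping),
#' and finally the optional scalebar band.
#'
#' @param spec A [phantom_spec()].
#' @return List with `image` (8-bit grayscale matrix) and `truth`, a tibble
#'   with one row per planted pore: `pore`, `center_x`, `center_y`,
#'   `semi_major`, `semi_minor`, `angle_deg`, `true_area` (`pi*a*b`),
#'   `true_perimeter` (Ramanujan), `on_border`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  W <- spec$width; H <- spec$height
  band_h <- if (!is.null(spec$scalebar_band)) spec$scalebar_band$height_px else 0
  usable_h <- H - band_h

  placed <- list()
  draw_pore <- function(on_border) {
    for (try in 1:2000) {
      b <- stats::runif(1, spec$semi_minor_range[1], spec$semi_minor_range[2])
      a <- min(b * stats::runif(1, spec$aspect_range[1], spec$aspect_range[2]),
               spec$max_semi_major)
      th <- if (identical(spec$angle, "uniform")) stats::runif(1, 0, 180)
            else as.numeric(spec$angle)
      if (on_border) {
        # centre on a randomly chosen vertical edge so the pore straddles it
        cx <- if (stats::runif(1) < 0.5) 0 else W - 1
        cy <- stats::runif(1, a + spec$min_gap, usable_h - 1 - a - spec$min_gap)
      } else {
        cx <- stats::runif(1, a + spec$min_gap, W - 1 - a - spec$min_gap)
        cy <- stats::runif(1, a + spec$min_gap, usable_h - 1 - a - spec$min_gap)
      }
      ok <- TRUE
      for (p in placed) {
        if (sqrt((cx - p$cx)^2 + (cy - p$cy)^2) < a + p$a + spec$min_gap) {
          ok <- FALSE; break
        }
      }
      if (ok) return(list(cx = cx, cy = cy, a = a, b = b, th = th,
                          border = on_border))
    }
    abort("could not place all pores with the requested clearance",
          class = "poremorph_infeasible_spec")
  }
  for (k in seq_len(spec$n_pores)) placed[[length(placed) + 1]] <- draw_pore(FALSE)
  for (k in seq_len(spec$n_border_pores)) placed[[length(placed) + 1]] <- draw_pore(TRUE)

  img <- matrix(spec$background_intensity + 0.0, H, W)
  for (p in placed) {
    x0 <- max(0, floor(p$cx - p$a - 1)); x1 <- min(W - 1, ceiling(p$cx + p$a + 1))
    y0 <- max(0, floor(p$cy - p$a - 1)); y1 <- min(H - 1, ceiling(p$cy + p$a + 1))
    xs <- x0:x1; ys <- y0:y1
    dx <- outer(rep(1, length(ys)), xs - p$cx)
    dy <- outer(ys - p$cy, rep(1, length(xs)))
    ct <- cos(p$th * pi / 180); st <- sin(p$th * pi / 180)
    u <- (dx * ct + dy * st) / p$a
    v <- (-dx * st + dy * ct) / p$b
    inside <- (u^2 + v^2) <= 1
    blk <- img[ys + 1, xs + 1]
    blk[inside] <- spec$pore_intensity
    img[ys + 1, xs + 1] <- blk
  }
  if (spec$illumination_gradient != 0) {
    ramp <- seq(-spec$illumination_gradient, spec$illumination_gradient,
                length.out = W)
    img <- img + matrix(ramp, H, W, byrow = TRUE)
  }
  if (spec$noise_sigma > 0) {
    img <- img + matrix(stats::rnorm(H * W, 0, spec$noise_sigma), H, W)
  }
  if (spec$salt_pepper > 0) {
    n_sp <- round(spec$salt_pepper * H * W)
    idx <- sample.int(H * W, n_sp)
    img[idx] <- ifelse(stats::runif(n_sp) < 0.5, 0, 255)
  }
  img <- pmin(pmax(round(img), 0), 255)
  if (band_h > 0) {
    img[(usable_h + 1):H, ] <- 0
    bar <- spec$scalebar_band$bar_px
    x0 <- max(1, floor((W - bar) / 2)); x1 <- min(W, x0 + bar - 1)
    rows <- usable_h + max(1, floor(band_h / 2)) + (-1:1)
    rows <- rows[rows >= 1 & rows <= H]
    img[rows, x0:x1] <- 255
  }
  truth <- tibble::tibble(
    pore = seq_along(placed),
    center_x = vapply(placed, `[[`, 1.0, "cx"),
    center_y = vapply(placed, `[[`, 1.0, "cy"),
    semi_major = vapply(placed, `[[`, 1.0, "a"),
    semi_minor = vapply(placed, `[[`, 1.0, "b"),
    angle_deg = vapply(placed, `[[`, 1.0, "th") %% 180,
    on_border = vapply(placed, `[[`, TRUE, "border")
  )
  truth$true_area <- pi * truth$semi_major * truth$semi_minor
  truth$true_perimeter <- ellipse_perimeter(truth$semi_major, truth$semi_minor)
  list(image = matrix(as.integer(img), H, W), truth = truth)
}

#' Score pipeline recovery against phantom ground truth
#'
#' Matches each accepted pore to the nearest ground-truth center (gated at
#' `min_gap / 2`) and reports recall, the mean relative area error, and the
#' mean angular error modulo 180 degrees. Angular errors are averaged over
#' planted pores with aspect ratio at least `min_aspect_for_angle`, since a
#' near-circular pore has no well-defined orientation. Accepted pores that
#' match no planted pore are counted as spurious.
#'
#' @param truth Ground-truth tibble from [generate_phantom()] (border pores
#'   are excluded from recall automatically).
#' @param records Measured pore records ([measure_pores()] output; pixel-mode
#'   scale so centers and areas are in px).
#' @param min_gap Matching gate, px (default the phantom default, 12).
#' @param min_aspect_for_angle Aspect threshold for angle scoring.
#' @return One-row tibble: `n_true`, `n_accepted`, `n_matched`, `recall`,
#'   `n_spurious`, `mean_area_error` (|measured - true| / true),
#'   `mean_angle_error_deg`.
#' @export
score_recovery <- function(truth, records, min_gap = 12,
                           min_aspect_for_angle = 1.15) {
  interior <- truth[!truth$on_border, , drop = FALSE]
  n_true <- nrow(interior)
  n_acc <- nrow(records)
  matched <- rep(NA_integer_, n_acc)
  if (n_acc && n_true) {
    for (k in seq_len(n_acc)) {
      d <- sqrt((interior$center_x - records$center_x[k])^2 +
                (interior$center_y - records$center_y[k])^2)
      j <- which.min(d)
      if (d[j] <= min_gap / 2) matched[k] <- j
    }
  }
  hit <- !is.na(matched)
  area_err <- angle_err <- numeric(0)
  if (any(hit)) {
    m <- interior[matched[hit], , drop = FALSE]
    r <- records[hit, , drop = FALSE]
    area_err <- abs(r$area_px - m$true_area) / m$true_area
    elong <- m$semi_major / m$semi_minor >= min_aspect_for_angle &
      !is.na(r$orientation_angle_deg)
    d <- abs(r$orientation_angle_deg[elong] - m$angle_deg[elong]) %% 180
    angle_err <- pmin(d, 180 - d)
  }
  tibble::tibble(
    n_true = n_true,
    n_accepted = n_acc,
    n_matched = length(unique(matched[hit])),
    recall = length(unique(matched[hit])) / n_true,
    n_spurious = sum(!hit),
    mean_area_error = if (length(area_err)) mean(area_err) else NA_real_,
    mean_angle_error_deg = if (length(angle_err)) mean(angle_err) else NA_real_
  )
}

#' Write a phantom image and its ground truth to disk
#'
#' @param phantom A [generate_phantom()] result.
#' @param image_path PNG output path.
#' @param truth_path CSV output path.
#' @return Invisibly, the two paths.
#' @export
write_phantom <- function(phantom, image_path, truth_path) {
  save_png(phantom$image, image_path)
  readr::write_csv(phantom$truth, truth_path, eol = "\n")
  invisible(c(image_path, truth_path))
}
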