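#' Summary statistics over a set of pore records
#'
#' The per-pass "Results box": pore count, smallest/largest/mean/median pore
#' area, sample standard deviation of area, mean perimeter, mean
#' isoperimetric ratio, and mean pore density (pore count divided by the full
#' analyzed image area, in pores per mm^2; omitted as `NA` in pixel mode).
#' Mean Feret diameters are included for CSV export even though an
#' interactive results box would not show them.
#'
#' @param records Tibble of pore records (from [measure_pores()] or
#'   [tidy.pore_session()]); must be nonempty.
#' @param scale A [make_scale()] object (for the density denominator).
#' @param image_dims `c(height, width)` of the analyzed image, px.
#' @return One-row tibble of summary statistics. With a single pore the
#'   standard deviation is reported as 0 and `degenerate_n` is `TRUE`.
#' @export
summarize_pores <- function(records, scale, image_dims) {
  if (!nrow(records))
    abort("no pore records to summarize", class = "poremorph_empty_summary")
  a <- records$area
  n <- length(a)
  density <- if (scale$mode == "pixel") NA_real_ else {
    convert_measurement(n / prod(image_dims), "inverse_area", scale)
  }
  tibble::tibble(
    n_pores = n,
    min_area = min(a),
    max_area = max(a),
    mean_area = mean(a),
    median_area = median(a),
    std_area = if (n > 1) sd(a) else 0,
    mean_perimeter = mean(records$perimeter),
    mean_ipr = mean(records$ipr),
    mean_density = density,
    mean_feret_min = mean(records$feret_min, na.rm = TRUE),
    mean_feret_max = mean(records$feret_max, na.rm = TRUE),
    degenerate_n = n < 2
  )
}

#' Session-level summary ("Results box")
#'
#' @param session A [pore_session()] with at least one pass.
#' @param which `"detected"` (current pass) or `"saved"`.
#' @return One-row tibble (see [summarize_pores()]).
#' @export
session_summary <- function(session, which = c("detected", "saved")) {
  which <- match.arg(which)
  recs <- session[[which]]
  if (!nrow(recs))
    abort(paste0("no ", which, " pores to summarize"),
          class = "poremorph_empty_summary")
  scale <- if (which == "detected") current_settings(session)$scale
           else session$passes[[recs$pass_id[1]]]$settings$scale
  summarize_pores(recs, scale, dim(session$image))
}

# frozen CSV column order
csv_columns <- c("pass_id", "pore_id", "area", "perimeter", "ipr",
                 "orientation_angle_deg", "orientation_vx", "orientation_vy",
                 "center_x", "center_y", "feret_min", "feret_max", "units",
                 "min_pore_size_px", "max_pore_size_px", "denoise_strength",
                 "denoise_size", "grayscale_threshold", "clahe_size",
                 "clahe_clip_limit", "scale_mode", "um_per_px")

#' Export pore records to CSV
#'
#' One row per pore with its measurements followed by the save-profile columns
#' of the pass that produced it. Header always present; comma-delimited,
#' UTF-8, LF line endings. The column order is fixed so exports from any
#' session are directly comparable.
#'
#' @param session A [pore_session()].
#' @param which `"detected"` or `"saved"`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_csv <- function(session, which = c("detected", "saved"), path) {
  which <- match.arg(which)
  recs <- records_with_profiles(session, which)
  if (!nrow(recs))
    abort(paste0("no ", which, " pores to export"),
          class = "poremorph_empty_summary")
  recs$vertices <- NULL
  recs <- recs[, csv_columns]
  out <- tryCatch(readr::write_csv(recs, path, eol = "\n"),
                  error = function(e)
                    abort(paste0("CSV export failed for path: ", path),
                          class = "poremorph_io"))
  invisible(path)
}

#' Read back an exported CSV
#'
#' @param path Path written by [export_csv()].
#' @return Tibble with the frozen column set.
#' @export
read_pore_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(units = "c", scale_mode = "c",
                                          .default = "d"))
}

#' Display settings for overlay rendering
#'
#' @param show_detected,show_saved,show_removed,show_numbers Toggles for the
#'   contour classes and the red number labels.
#' @param orientation_mode `"none"`, `"orientation"` (the orientation
#'   segment), `"major_axis"`, `"minor_axis"` or `"ellipse"`.
#' @param underlay Which image to draw over: `"original"`, `"clahe"`,
#'   `"denoised"` or `"threshold"`.
#' @return A `display_settings` list.
#' @export
display_settings <- function(show_detected = TRUE, show_saved = TRUE,
                             show_removed = FALSE, show_numbers = FALSE,
                             orientation_mode = c("none", "orientation",
                                                  "major_axis", "minor_axis",
                                                  "ellipse"),
                             underlay = c("original", "clahe", "denoised",
                                          "threshold")) {
  structure(list(show_detected = show_detected, show_saved = show_saved,
                 show_removed = show_removed, show_numbers = show_numbers,
                 orientation_mode = match.arg(orientation_mode),
                 underlay = match.arg(underlay)),
            class = "display_settings")
}

overlay_palette <- function() {
  list(detected = c(0, 255, 0),        # green
       saved = c(255, 215, 0),         # gold
       removed_size = c(0, 0, 255),    # blue
       removed_hierarchy = c(255, 0, 255), # magenta
       removed_user = c(255, 165, 0),  # orange
       label = c(255, 0, 0))           # red
}

#' Render an annotation overlay as an RGB image
#'
#' Draws the session's contours over the chosen underlay: detected green,
#' saved gold, removed-by-size blue, removed-by-hierarchy magenta,
#' removed-by-user orange, with optional red number labels and per-pore
#' orientation glyphs. Pure function of the session and display settings.
#'
#' @param session A [pore_session()] with at least one pass.
#' @param display A [display_settings()] object.
#' @return H x W x 3 numeric array of 8-bit RGB values.
#' @export
render_overlay <- function(session, display = display_settings()) {
  if (!length(session$passes))
    abort("run a pass before rendering an overlay", class = "poremorph_state")
  pass <- session$passes[[length(session$passes)]]
  under <- switch(display$underlay,
                  original = session$image,
                  clahe = pass$images$clahe,
                  denoised = pass$images$denoised,
                  threshold = ifelse(unclass(pass$images$binary), 0, 255))
  h <- nrow(under); w <- ncol(under)
  rgb <- array(as.numeric(under), c(h, w, 3))
  pal <- overlay_palette()

  paint <- function(rgb, xy, col) {
    keep <- xy[, 1] >= 0 & xy[, 1] < w & xy[, 2] >= 0 & xy[, 2] < h
    xy <- xy[keep, , drop = FALSE]
    if (!nrow(xy)) return(rgb)
    for (ch in 1:3) rgb[cbind(xy[, 2] + 1L, xy[, 1] + 1L, ch)] <- col[ch]
    rgb
  }

  draw_records <- function(rgb, recs, col) {
    if (!nrow(recs)) return(rgb)
    for (k in seq_len(nrow(recs))) {
      rgb <- paint(rgb, recs$vertices[[k]], col)
      rgb <- draw_orientation(rgb, recs[k, ], display$orientation_mode, col, paint)
      if (display$show_numbers) {
        rgb <- draw_number(rgb, recs$pore_id[k],
                           recs$center_x[k], recs$center_y[k], pal$label, paint)
      }
    }
    rgb
  }

  if (display$show_removed) {
    det <- pass$detection
    for (st in c("removed_size", "removed_hierarchy")) {
      rows <- det[det$status == st, , drop = FALSE]
      for (k in seq_len(nrow(rows))) rgb <- paint(rgb, rows$vertices[[k]], pal[[st]])
    }
    if (nrow(session$removed_user)) {
      for (k in seq_len(nrow(session$removed_user)))
        rgb <- paint(rgb, session$removed_user$vertices[[k]], pal$removed_user)
    }
  }
  if (display$show_saved) rgb <- draw_records(rgb, session$saved, pal$saved)
  if (display$show_detected) rgb <- draw_records(rgb, session$detected, pal$detected)
  rgb
}

# orientation glyphs: segment along the major axis (length = vector magnitude
# for "orientation", full axes otherwise) or the fitted ellipse outline
draw_orientation <- function(rgb, rec, mode, col, paint) {
  if (mode == "none" || is.na(rec$orientation_angle_deg)) return(rgb)
  cx <- rec$center_x; cy <- rec$center_y
  th <- rec$orientation_angle_deg * pi / 180
  seg <- function(len, ang) {
    t <- seq(-len / 2, len / 2, length.out = max(2, ceiling(len * 2)))
    cbind(round(cx + t * cos(ang)), round(cy + t * sin(ang)))
  }
  maj <- rec$feret_max_px
  min_ <- rec$feret_min_px
  xy <- switch(mode,
    orientation = seg(sqrt(rec$orientation_vx^2 + rec$orientation_vy^2), th),
    major_axis = seg(maj, th),
    minor_axis = seg(min_, th + pi / 2),
    ellipse = {
      t <- seq(0, 2 * pi, length.out = 720)
      a <- maj / 2; b <- min_ / 2
      cbind(round(cx + a * cos(t) * cos(th) - b * sin(t) * sin(th)),
            round(cy + a * cos(t) * sin(th) + b * sin(t) * cos(th)))
    })
  paint(rgb, xy, col)
}

# 3 x 5 bitmap digits for the red number labels
digit_font <- function() {
  rows <- list(
    "0" = c("111","101","101","101","111"),
    "1" = c("010","110","010","010","111"),
    "2" = c("111","001","111","100","111"),
    "3" = c("111","001","111","001","111"),
    "4" = c("101","101","111","001","001"),
    "5" = c("111","100","111","001","111"),
    "6" = c("111","100","111","101","111"),
    "7" = c("111","001","010","010","010"),
    "8" = c("111","101","111","101","111"),
    "9" = c("111","101","111","001","111"))
  lapply(rows, function(r) {
    do.call(rbind, lapply(r, function(s) as.integer(strsplit(s, "")[[1]]) == 1L))
  })
}

draw_number <- function(rgb, num, cx, cy, col, paint, scale = 2L) {
  font <- digit_font()
  digits <- strsplit(as.character(num), "")[[1]]
  x0 <- round(cx) - (length(digits) * 4 * scale) %/% 2
  y0 <- round(cy) - (5 * scale) %/% 2
  for (d in seq_along(digits)) {
    g <- font[[digits[d]]]
    px <- which(g, arr.ind = TRUE) # row, col of lit cells
    if (!nrow(px)) next
    cells <- expand.grid(sy = 0:(scale - 1), sx = 0:(scale - 1))
    for (cc in seq_len(nrow(cells))) {
      xy <- cbind(x0 + (d - 1) * 4 * scale + (px[, 2] - 1) * scale + cells$sx[cc],
                  y0 + (px[, 1] - 1) * scale + cells$sy[cc])
      rgb <- paint(rgb, xy, col)
    }
  }
  rgb
}

#' Plot a session's contours, colored by status
#'
#' A ggplot rendering of the same color semantics as [render_overlay()]:
#' detected green, saved gold, removed-by-size blue, removed-by-hierarchy
#' magenta, removed-by-user orange, on the image's coordinate frame (y axis
#' reversed to match image rows).
#'
#' @param object A [pore_session()] with at least one pass.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pore_session <- function(object, ...) {
  if (!length(object$passes))
    abort("run a pass before plotting", class = "poremorph_state")
  det <- object$passes[[length(object$passes)]]$detection
  poly <- function(recs, status) {
    if (!nrow(recs)) return(NULL)
    purrr::list_rbind(purrr::map(seq_len(nrow(recs)), function(k) {
      v <- recs$vertices[[k]]
      tibble::tibble(x = v[, 1], y = v[, 2],
                     id = paste0(status, "_", k), status = status)
    }))
  }
  df <- dplyr::bind_rows(
    poly(det[det$status == "removed_size", ], "removed_size"),
    poly(det[det$status == "removed_hierarchy", ], "removed_hierarchy"),
    poly(object$removed_user, "removed_user"),
    poly(object$saved, "saved"),
    poly(object$detected, "detected")
  )
  cols <- c(detected = "#00FF00", saved = "#FFD700", removed_size = "#0000FF",
            removed_hierarchy = "#FF00FF", removed_user = "#FFA500")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   group = .data$id, color = .data$status)) +
    ggplot2::geom_path(linewidth = 0.4) +
    ggplot2::scale_color_manual(values = cols) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (px)", y = "y (px)", color = "contour status") +
    ggplot2::theme_minimal()
}

#' Histogram of pore areas
#'
#' @param records Pore records tibble (e.g. `tidy(session)`).
#' @param bins Number of histogram bins.
#' @return A ggplot object.
#' @export
plot_pore_areas <- function(records, bins = 30) {
  ggplot2::ggplot(records, ggplot2::aes(x = .data$area)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey30") +
    ggplot2::labs(x = paste0("pore area (", records$units[1], "^2)"),
                  y = "count") +
    ggplot2::theme_minimal()
}
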