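#' Trace contours of black regions with their containment hierarchy
#'
#' Border following after Suzuki and Abe: a raster scan traces every boundary
#' loop between black (pore candidate) and white pixels, returning the ordered
#' (x, y) boundary pixels of each loop together with the containment
#' hierarchy. Black regions are 8-connected (white background 4-connected).
#' Every black region yields exactly one outer contour; holes and nested
#' regions yield further contours whose `parent_id` links point outward.
#'
#' @param bin A `binary_image` from [apply_threshold()], or a logical matrix
#'   with `TRUE` = black.
#' @return A tibble with one row per contour: `contour_id`, `parent_id` (`NA`
#'   for top-level contours), `is_hole`, `touches_border`, `n_vertices`, and a
#'   `vertices` list-column of n x 2 matrices of 0-based (x, y) coordinates.
#' @export
trace_contours <- function(bin) {
  bin <- check_binary(bin)
  res <- .trace_borders_cpp(matrix(as.integer(bin), nrow(bin), ncol(bin)))
  n <- length(res$vertices)
  tibble::tibble(
    contour_id = seq_len(n),
    parent_id = ifelse(res$parent == 0L, NA_integer_, res$parent),
    is_hole = res$is_hole == 1L,
    touches_border = res$touches_border,
    n_vertices = vapply(res$vertices, nrow, 1L),
    vertices = lapply(res$vertices, function(m) {
      colnames(m) <- c("x", "y")
      m
    })
  )
}

check_binary <- function(bin) {
  if (inherits(bin, "binary_image")) return(bin)
  if (is.matrix(bin) && is.logical(bin)) return(bin)
  if (is.matrix(bin) && is.numeric(bin) && all(bin %in% c(0, 1)))
    return(bin == 1)
  abort("input must be a binary image (logical matrix or binary_image)",
        class = "poremorph_contract")
}

#' Partition traced contours into accepted and removed sets
#'
#' Contours that touch the image border or lie inside another contour (any
#' non-top-level contour: holes and all nested descendants) are rejected on
#' hierarchy grounds; of the remainder, those with enclosed area outside the
#' `[min, max]` pixel gates are rejected on size. The hierarchy/border rule is
#' applied before the size gate. Size gates compare the enclosed-pixel area of
#' the black region (px^2).
#'
#' @param contours Tibble from [trace_contours()].
#' @param min_pore_size_px,max_pore_size_px Area gates in px^2.
#' @param bin The binary image the contours were traced from (used for
#'   enclosed-pixel areas).
#' @return A `pore_detection` tibble: the input plus `area_px` and a `status`
#'   column in `accepted` / `removed_size` / `removed_hierarchy`. The three
#'   statuses partition the traced set.
#' @export
filter_contours <- function(contours, min_pore_size_px, max_pore_size_px, bin) {
  bin <- check_binary(bin)
  lab <- .label_regions_cpp(matrix(as.integer(bin), nrow(bin), ncol(bin)))
  area_of <- function(v) {
    id <- lab$labels[v[1, "y"] + 1L, v[1, "x"] + 1L]
    if (id == 0) 0 else lab$count[id]
  }
  out <- contours
  out$area_px <- vapply(out$vertices, area_of, 1.0)
  hier <- !is.na(out$parent_id) | out$is_hole | out$touches_border
  size <- !hier & (out$area_px < min_pore_size_px | out$area_px > max_pore_size_px)
  out$status <- dplyr::case_when(hier ~ "removed_hierarchy",
                                 size ~ "removed_size",
                                 TRUE ~ "accepted")
  class(out) <- c("pore_detection", class(out))
  attr(out, "image_dims") <- dim(bin)
  out
}

#' Detect pores in a binary image
#'
#' Convenience wrapper: [trace_contours()] followed by [filter_contours()].
#'
#' @inheritParams filter_contours
#' @param settings A [pore_settings()] bundle supplying the size gates.
#' @return A `pore_detection` tibble.
#' @export
detect_pores <- function(bin, settings) {
  filter_contours(trace_contours(bin),
                  settings$min_pore_size_px, settings$max_pore_size_px, bin)
}
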