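#' Shoelace area of a contour polygon
#'
#' Absolute area of the polygon through the contour vertices (Green's
#' theorem / shoelace formula), independent of traversal direction. On dense
#' digitized boundaries this underestimates the enclosed-pixel area by roughly
#' half the perimeter because vertices are pixel centers; [measure_pores()]
#' therefore reports enclosed-pixel areas, while this function implements the
#' plain polygon definition.
#'
#' @param vertices n x 2 matrix of (x, y) vertices, or a single-row contour.
#' @return Area in px^2 (0 for fewer than 3 vertices).
#' @export
polygon_area <- function(vertices) {
  v <- as_vertex_matrix(vertices)
  n <- nrow(v)
  if (n < 1) abort("contour needs at least one vertex", class = "poremorph_contract")
  if (n < 3) return(0)
  x <- v[, 1]; y <- v[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  abs(sum(x * yn - xn * y)) / 2
}

#' Euclidean perimeter of a contour polygon
#'
#' Sum of the Euclidean edge lengths around the closed loop (the closing edge
#' from last to first vertex included).
#'
#' @inheritParams polygon_area
#' @return Perimeter in px (0 for fewer than 2 vertices).
#' @export
polygon_perimeter <- function(vertices) {
  v <- as_vertex_matrix(vertices)
  n <- nrow(v)
  if (n < 2) return(0)
  xn <- c(v[-1, 1], v[1, 1]); yn <- c(v[-1, 2], v[1, 2])
  sum(sqrt((v[, 1] - xn)^2 + (v[, 2] - yn)^2))
}

# Perimeter estimate for dense 8-connected boundary chains with the Kulpa
# digitization correction (0.948 per axial step, 1.340 per diagonal step):
# the plain (1, sqrt(2)) chain length overestimates smooth boundaries by ~5%.
chain_perimeter <- function(vertices) {
  v <- as_vertex_matrix(vertices)
  n <- nrow(v)
  if (n < 2) return(0)
  dx <- abs(c(v[-1, 1], v[1, 1]) - v[, 1])
  dy <- abs(c(v[-1, 2], v[1, 2]) - v[, 2])
  diag <- dx == 1 & dy == 1
  axial <- (dx + dy) == 1
  if (any(dx > 1 | dy > 1)) {
    # not a unit chain: fall back to plain Euclidean edges
    return(polygon_perimeter(v))
  }
  0.948 * sum(axial) + 1.340 * sum(diag)
}

as_vertex_matrix <- function(v) {
  if (is.matrix(v) && ncol(v) == 2) return(v)
  abort("vertices must be an n x 2 matrix of (x, y) coordinates",
        class = "poremorph_contract")
}

#' Isoperimetric ratio
#'
#' Disc-normalized compactness `4 * pi * area / perimeter^2`: exactly 1 for a
#' circle, `pi/4` for a square, and smaller the more elongated or irregular
#' the shape. Cryogel pores typically average around 0.5-0.6 (moderately
#' elongated).
#'
#' @param area Area (px^2 or um^2).
#' @param perimeter Perimeter in matching linear units (> 0).
#' @return Dimensionless ratio.
#' @export
isoperimetric_ratio <- function(area, perimeter) {
  if (any(perimeter <= 0))
    abort("isoperimetric ratio undefined for zero perimeter",
          class = "poremorph_undefined_ipr")
  4 * pi * area / perimeter^2
}

#' Direct least-squares ellipse fit
#'
#' Fits a conic constrained to be an ellipse (Fitzgibbon's direct
#' least-squares method, in the numerically stable Halir-Flusser form) to the
#' contour vertices. Recovery is exact (to floating precision) when the
#' points lie on an ellipse.
#'
#' @inheritParams polygon_area
#' @return A list with `center` (x, y), `major_len` and `minor_len` (full axis
#'   lengths, px) and `angle_deg` (major-axis angle from +x, y downward, in
#'   \[0, 180)).
#' @export
fit_ellipse <- function(vertices) {
  v <- as_vertex_matrix(vertices)
  v <- unique(v)
  if (nrow(v) < 5)
    abort("ellipse fit needs at least 5 distinct points",
          class = "poremorph_fit_impossible")
  mx <- mean(v[, 1]); my <- mean(v[, 2])
  x <- v[, 1] - mx; y <- v[, 2] - my
  D1 <- cbind(x^2, x * y, y^2)
  D2 <- cbind(x, y, 1)
  S1 <- crossprod(D1); S2 <- crossprod(D1, D2); S3 <- crossprod(D2)
  Tm <- tryCatch(-solve(S3, t(S2)),
                 error = function(e) abort("degenerate point configuration",
                                           class = "poremorph_fit_impossible"))
  M <- S1 + S2 %*% Tm
  M <- rbind(M[3, ] / 2, -M[2, ], M[1, ] / 2)
  e <- eigen(M)
  vec <- Re(e$vectors)
  cond <- 4 * vec[1, ] * vec[3, ] - vec[2, ]^2
  ok <- which(cond > 0)
  if (!length(ok))
    abort("no elliptical solution for these points",
          class = "poremorph_fit_impossible")
  a1 <- vec[, ok[1]]
  coef <- c(a1, as.vector(Tm %*% a1)) # A B C D E F for conic on centered coords
  names(coef) <- c("A", "B", "C", "D", "E", "F")
  A <- coef["A"]; B <- coef["B"] / 2; C <- coef["C"]
  D <- coef["D"] / 2; E <- coef["E"] / 2; F <- coef["F"]
  # conic center
  den <- A * C - B^2
  cx <- (B * E - C * D) / den
  cy <- (B * D - A * E) / den
  # axes from the quadratic form at the center
  Fc <- A * cx^2 + 2 * B * cx * cy + C * cy^2 + 2 * D * cx + 2 * E * cy + F
  lam <- eigen(matrix(c(A, B, B, C), 2), symmetric = TRUE)
  semi2 <- -Fc / lam$values
  if (any(semi2 <= 0))
    abort("no elliptical solution for these points",
          class = "poremorph_fit_impossible")
  semi <- sqrt(semi2)
  ord <- order(semi, decreasing = TRUE)
  major_axis <- lam$vectors[, ord[1]]
  ang <- atan2(major_axis[2], major_axis[1]) * 180 / pi
  ang <- ang %% 180
  list(center = c(x = unname(cx + mx), y = unname(cy + my)),
       major_len = unname(2 * semi[ord[1]]),
       minor_len = unname(2 * semi[ord[2]]),
       angle_deg = unname(ang))
}

#' Orientation vector of a fitted ellipse
#'
#' Pores carry no inherent direction, so all are taken to point rightward:
#' the angle is normalized to \[0, 180) from the +x axis (y downward). The
#' vector points along the major axis with magnitude `major_len - minor_len`,
#' so circular pores have zero orientation.
#'
#' @param fit A [fit_ellipse()] result.
#' @return List with `vector` (vx, vy) and `angle_deg`.
#' @export
orientation_vector <- function(fit) {
  m <- fit$major_len - fit$minor_len
  ang <- fit$angle_deg %% 180
  list(vector = c(vx = m * cos(ang * pi / 180), vy = m * sin(ang * pi / 180)),
       angle_deg = ang)
}

#' Interior-pixel centroid of a contour
#'
#' Arithmetic mean of the (x, y) coordinates of all pixels of the black
#' region the contour bounds (interior plus boundary). Falls back to the mean
#' of the contour vertices if the contour bounds no black pixel.
#'
#' @inheritParams polygon_area
#' @param bin The binary image the contour was traced from.
#' @return Numeric `c(x, y)`, 0-based pixel coordinates.
#' @export
centroid <- function(vertices, bin) {
  v <- as_vertex_matrix(vertices)
  bin <- check_binary(bin)
  lab <- .label_regions_cpp(matrix(as.integer(bin), nrow(bin), ncol(bin)))
  id <- lab$labels[v[1, 2] + 1L, v[1, 1] + 1L]
  if (id == 0) {
    warn("contour bounds no black pixel; centroid falls back to vertex mean")
    return(c(x = mean(v[, 1]), y = mean(v[, 2])))
  }
  c(x = lab$sum_x[id] / lab$count[id], y = lab$sum_y[id] / lab$count[id])
}

#' Measure every accepted pore of a detection
#'
#' Computes, per accepted contour: enclosed-pixel area, digitization-corrected
#' perimeter, isoperimetric ratio, interior-pixel centroid, fitted-ellipse
#' parameters, orientation vector/angle, and Feret diameters (taken from the
#' fitted ellipse axes). Lengths and areas are converted through the scale;
#' in pixel mode they stay in px / px^2 and the `units` column says `"px"`.
#' Contours with fewer than 5 distinct vertices cannot carry an ellipse fit;
#' their orientation and Feret fields are `NA`.
#'
#' @param detection A `pore_detection` tibble from [detect_pores()] (or any
#'   contour tibble with a `vertices` list-column).
#' @param bin The binary image the contours were traced from.
#' @param scale A [make_scale()] object.
#' @return A tibble, one row per accepted pore: `pore_id`, `area`,
#'   `perimeter`, `ipr`, `orientation_angle_deg`, `orientation_vx`,
#'   `orientation_vy`, `center_x`, `center_y`, `feret_min`, `feret_max`,
#'   `units`, plus pixel-space columns `area_px`, `perimeter_px`.
#' @export
measure_pores <- function(detection, bin, scale = make_scale("pixel")) {
  bin <- check_binary(bin)
  rows <- if ("status" %in% names(detection)) {
    detection[detection$status == "accepted", , drop = FALSE]
  } else detection
  lab <- .label_regions_cpp(matrix(as.integer(bin), nrow(bin), ncol(bin)))
  f_len <- function(v) convert_measurement(v, "length", scale)
  f_area <- function(v) convert_measurement(v, "area", scale)
  units <- if (scale$mode == "pixel") "px" else "um"

  one <- function(v) {
    id <- lab$labels[v[1, 2] + 1L, v[1, 1] + 1L]
    area_px <- if (id > 0) lab$count[id] else max(polygon_area(v), 1)
    per_px <- chain_perimeter(v)
    if (per_px == 0) per_px <- 2 # a single pixel still has a finite boundary
    ctr <- if (id > 0) {
      c(lab$sum_x[id] / lab$count[id], lab$sum_y[id] / lab$count[id])
    } else c(mean(v[, 1]), mean(v[, 2]))
    fit <- tryCatch(fit_ellipse(v), condition = function(e) NULL)
    if (!is.null(fit)) {
      ov <- orientation_vector(fit)
      tibble::tibble(
        area_px = area_px, perimeter_px = per_px,
        center_x = ctr[1], center_y = ctr[2],
        orientation_angle_deg = ov$angle_deg,
        orientation_vx = unname(ov$vector["vx"]),
        orientation_vy = unname(ov$vector["vy"]),
        feret_min_px = fit$minor_len, feret_max_px = fit$major_len
      )
    } else {
      tibble::tibble(
        area_px = area_px, perimeter_px = per_px,
        center_x = ctr[1], center_y = ctr[2],
        orientation_angle_deg = NA_real_, orientation_vx = NA_real_,
        orientation_vy = NA_real_, feret_min_px = NA_real_,
        feret_max_px = NA_real_
      )
    }
  }
  if (nrow(rows) == 0) {
    return(tibble::tibble(
      pore_id = integer(), area = numeric(), perimeter = numeric(),
      ipr = numeric(), orientation_angle_deg = numeric(),
      orientation_vx = numeric(), orientation_vy = numeric(),
      center_x = numeric(), center_y = numeric(), feret_min = numeric(),
      feret_max = numeric(), units = character(), area_px = numeric(),
      perimeter_px = numeric(), feret_min_px = numeric(),
      feret_max_px = numeric()
    ))
  }
  meas <- purrr::list_rbind(purrr::map(rows$vertices, one))
  out <- tibble::tibble(
    pore_id = seq_len(nrow(rows)),
    area = f_area(meas$area_px),
    perimeter = f_len(meas$perimeter_px),
    ipr = isoperimetric_ratio(meas$area_px, meas$perimeter_px),
    orientation_angle_deg = meas$orientation_angle_deg,
    orientation_vx = meas$orientation_vx,
    orientation_vy = meas$orientation_vy,
    center_x = meas$center_x,
    center_y = meas$center_y,
    feret_min = f_len(meas$feret_min_px),
    feret_max = f_len(meas$feret_max_px),
    units = units,
    area_px = meas$area_px,
    perimeter_px = meas$perimeter_px,
    feret_min_px = meas$feret_min_px,
    feret_max_px = meas$feret_max_px
  )
  if (nrow(rows)) out$vertices <- rows$vertices
  out
}
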