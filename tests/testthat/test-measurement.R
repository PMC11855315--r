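test_that("shoelace area and Euclidean perimeter match closed forms", {
  tri <- cbind(c(0, 4, 0), c(0, 0, 3))
  expect_equal(polygon_area(tri), 6)
  rect <- cbind(c(0, 10, 10, 0), c(0, 0, 5, 5))
  expect_equal(polygon_area(rect), 50)
  sq <- cbind(c(0, 10, 10, 0), c(0, 0, 10, 10))
  expect_equal(polygon_perimeter(sq), 40)
  expect_equal(polygon_perimeter(cbind(c(0, 3), c(0, 4))), 10) # there and back
  expect_equal(polygon_area(cbind(c(0, 3), c(0, 4))), 0)
  expect_error(polygon_area(cbind(numeric(), numeric())),
               class = "poremorph_contract")
})

test_that("shoelace area agrees with pixel counting within perimeter/2 + 1", {
  set.seed(101)
  for (k in 1:100) {
    v <- random_simple_polygon(n = sample(5:14, 1))
    a_shoe <- polygon_area(v)
    a_pix <- pixel_count_area_oracle(v[, 1], v[, 2])
    bound <- polygon_perimeter(v) / 2 + 1
    expect_lte(abs(a_shoe - a_pix), bound)
  }
})

test_that("the digitized-circle chain perimeter is within 5% of 2*pi*r", {
  b <- raster_ellipse(121, 121, 60, 60, 50, 50)
  v <- trace_contours(b)$vertices[[1]]
  expect_lt(abs(polygon_perimeter(v) - 2 * pi * 50) / (2 * pi * 50), 0.05)
})

test_that("isoperimetric ratio hits its closed forms", {
  r <- 7.3
  expect_equal(isoperimetric_ratio(pi * r^2, 2 * pi * r), 1)
  s <- 11
  expect_equal(isoperimetric_ratio(s^2, 4 * s), pi / 4)
  # 2:1 ellipse, Ramanujan perimeter pi*(9 - sqrt(35)) for a=2, b=1
  p <- pi * (9 - sqrt(35))
  expect_equal(isoperimetric_ratio(2 * pi, p), 8 * pi^2 / p^2)
  expect_equal(isoperimetric_ratio(2 * pi, p), 0.84, tolerance = 0.01)
  expect_error(isoperimetric_ratio(10, 0), class = "poremorph_undefined_ipr")
})

test_that("ellipse fitting recovers exact parameters from sampled points", {
  t <- seq(0, 2 * pi, length.out = 37)[-37]
  th <- 25 * pi / 180
  v <- cbind(50 + 30 * cos(t) * cos(th) - 12 * sin(t) * sin(th),
             40 + 30 * cos(t) * sin(th) + 12 * sin(t) * cos(th))
  f <- fit_ellipse(v)
  expect_equal(unname(f$center), c(50, 40), tolerance = 1e-6)
  expect_equal(f$major_len, 60, tolerance = 1e-6)
  expect_equal(f$minor_len, 24, tolerance = 1e-6)
  expect_equal(f$angle_deg, 25, tolerance = 1e-6)
})

test_that("circles fit with equal axes and few points refuse to fit", {
  t <- seq(0, 2 * pi, length.out = 13)[-13]
  f <- fit_ellipse(cbind(10 + 5 * cos(t), -3 + 5 * sin(t)))
  expect_equal(f$major_len, f$minor_len, tolerance = 1e-9)
  expect_error(fit_ellipse(cbind(c(0, 1, 2, 3), c(0, 1, 0, 1))),
               class = "poremorph_fit_impossible")
  # 5 points but only 4 distinct
  expect_error(fit_ellipse(cbind(c(0, 1, 2, 3, 0), c(0, 1, 0, 1, 0))),
               class = "poremorph_fit_impossible")
})

test_that("orientation vectors follow the pointing-right convention", {
  ov <- orientation_vector(list(major_len = 20, minor_len = 10, angle_deg = 0))
  expect_equal(unname(ov$vector), c(10, 0))
  expect_equal(ov$angle_deg, 0)
  circ <- orientation_vector(list(major_len = 15, minor_len = 15, angle_deg = 77))
  expect_equal(unname(circ$vector), c(0, 0))
  neg <- orientation_vector(list(major_len = 9, minor_len = 4, angle_deg = -30))
  expect_equal(neg$angle_deg, 150)
  expect_equal(sqrt(sum(neg$vector^2)), 5)
})

test_that("centroids equal the brute-force interior pixel mean", {
  b <- raster_rect(40, 40, 11, 20, 11, 20) # rows/cols 10..19 0-based
  v <- trace_contours(b)$vertices[[1]]
  expect_equal(unname(centroid(v, b)), c(14.5, 14.5))
  # right triangle: compare against a full pixel scan
  tri <- matrix(FALSE, 40, 40)
  for (i in 1:20) tri[10 + i, 11:(10 + i)] <- TRUE
  vt <- trace_contours(tri)$vertices[[1]]
  px <- which(tri, arr.ind = TRUE)
  expect_equal(unname(centroid(vt, tri)),
               c(mean(px[, 2]) - 1, mean(px[, 1]) - 1))
  one <- matrix(FALSE, 10, 10); one[4, 8] <- TRUE
  vo <- trace_contours(one)$vertices[[1]]
  expect_equal(unname(centroid(vo, one)), c(7, 3))
})

test_that("measure_pores composes measurements and converts units", {
  b <- raster_rect(60, 60, 21, 40, 21, 40) # 20x20 square region
  det <- filter_contours(trace_contours(b), 1, 1e9, b)
  s <- make_scale("supplied", 200, 100) # 0.5 um/px
  m <- measure_pores(det, b, s)
  expect_equal(m$area, 400 * 0.25) # enclosed-pixel area in um^2
  expect_equal(m$units, "um")
  mpx <- measure_pores(det, b, make_scale("pixel"))
  expect_equal(mpx$units, "px")
  expect_equal(mpx$area, 400)
  # scale equivariance: converting pixel measurements reproduces um ones
  expect_equal(convert_measurement(mpx$area, "area", s), m$area)
  expect_equal(convert_measurement(mpx$perimeter, "length", s), m$perimeter)
  expect_equal(convert_measurement(mpx$feret_max, "length", s), m$feret_max)
})

test_that("digitized circular pores have near-unit IPR and ellipse-axis ferets", {
  b <- raster_ellipse(101, 101, 50, 50, 30, 30)
  det <- filter_contours(trace_contours(b), 1, 1e9, b)
  m <- measure_pores(det, b)
  expect_gt(m$ipr, 0.95)
  expect_lt(m$ipr, 1.05)
  expect_equal(m$feret_max, m$feret_max_px)
  expect_equal(m$feret_min_px, m$feret_max_px, tolerance = 0.05)
  expect_equal(m$feret_max_px, 60, tolerance = 0.05 * 60)
})

test_that("area, perimeter and IPR are rotation invariant within digitization error", {
  # at the phantom's upper pore scale; digitization error shrinks with size
  ref <- NULL
  for (th in c(0, 25, 60, 115, 170)) {
    b <- raster_ellipse(160, 160, 79.5, 79.5, 40, 16, th)
    det <- filter_contours(trace_contours(b), 1, 1e9, b)
    m <- measure_pores(det, b)
    d <- abs(m$orientation_angle_deg - th) %% 180
    expect_lte(min(d, 180 - d), 2)
    if (is.null(ref)) ref <- m
    expect_lt(abs(m$area_px - ref$area_px) / ref$area_px, 0.02)
    expect_lt(abs(m$perimeter_px - ref$perimeter_px) / ref$perimeter_px, 0.02)
    expect_lt(abs(m$ipr - ref$ipr) / ref$ipr, 0.02)
  }
})

test_that("tiny contours yield NA orientation instead of failing", {
  b <- matrix(FALSE, 12, 12); b[5:6, 5:6] <- TRUE # 4 boundary pixels
  det <- filter_contours(trace_contours(b), 1, 1e9, b)
  m <- measure_pores(det, b)
  expect_true(is.na(m$orientation_angle_deg))
  expect_true(is.na(m$feret_max))
  expect_equal(m$area_px, 4)
})
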