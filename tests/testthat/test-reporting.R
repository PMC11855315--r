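test_that("summary statistics match hand-computed values", {
  recs <- tibble::tibble(area = c(100, 200, 300), perimeter = c(30, 40, 50),
                         ipr = c(0.5, 0.6, 0.7), feret_min = c(5, 6, 7),
                         feret_max = c(9, 10, 11))
  s <- summarize_pores(recs, make_scale("supplied", 100, 100), c(1000, 1000))
  expect_equal(s$n_pores, 3)
  expect_equal(s$mean_area, 200)
  expect_equal(s$median_area, 200)
  expect_equal(s$std_area, 100) # sample sd of an arithmetic sequence
  expect_equal(s$min_area, 100)
  expect_equal(s$max_area, 300)
  expect_true(s$min_area <= s$median_area && s$median_area <= s$max_area)
})

test_that("pore density divides the count by the converted image area", {
  recs <- tibble::tibble(area = rep(10, 50), perimeter = 1, ipr = 1,
                         feret_min = 1, feret_max = 1)
  s <- summarize_pores(recs, make_scale("supplied", 2, 1), c(1000, 2000))
  expect_equal(s$mean_density, 100) # 50 pores / 0.5 mm^2
  spx <- summarize_pores(recs, make_scale("pixel"), c(1000, 2000))
  expect_true(is.na(spx$mean_density))
})

test_that("a single pore is summarized with zero sd and a degenerate flag", {
  recs <- tibble::tibble(area = 42, perimeter = 10, ipr = 0.9,
                         feret_min = 2, feret_max = 3)
  s <- summarize_pores(recs, make_scale("pixel"), c(100, 100))
  expect_equal(s$std_area, 0)
  expect_true(s$degenerate_n)
  expect_error(summarize_pores(recs[0, ], make_scale("pixel"), c(10, 10)),
               class = "poremorph_empty_summary")
})

test_that("the results box exposes exactly the documented statistics", {
  ph <- small_phantom(seed = 17)
  s <- run_pass(pore_session(ph$image), pore_settings(
    denoise_strength = 0, scale = make_scale("supplied", 200, 100)))
  box <- session_summary(s, "detected")
  expect_named(box, c("n_pores", "min_area", "max_area", "mean_area",
                      "median_area", "std_area", "mean_perimeter", "mean_ipr",
                      "mean_density", "mean_feret_min", "mean_feret_max",
                      "degenerate_n"))
  expect_false(is.na(box$mean_density))
  expect_error(session_summary(s, "saved"), class = "poremorph_empty_summary")
})

test_that("CSV export freezes the schema and round-trips numerics", {
  ph <- small_phantom(seed = 17)
  s <- run_pass(pore_session(ph$image), pore_settings(
    denoise_strength = 0, scale = make_scale("supplied", 200, 100)))
  f <- withr::local_tempfile(fileext = ".csv")
  export_csv(s, "detected", f)
  lines <- readLines(f)
  expect_equal(lines[1], paste(
    "pass_id,pore_id,area,perimeter,ipr,orientation_angle_deg,orientation_vx",
    "orientation_vy,center_x,center_y,feret_min,feret_max,units",
    "min_pore_size_px,max_pore_size_px,denoise_strength,denoise_size",
    "grayscale_threshold,clahe_size,clahe_clip_limit,scale_mode,um_per_px",
    sep = ","))
  expect_equal(length(lines), nrow(s$detected) + 1)
  back <- read_pore_csv(f)
  expect_equal(back$area, s$detected$area, tolerance = 1e-9)
  expect_equal(back$ipr, s$detected$ipr, tolerance = 1e-9)
  expect_equal(back$um_per_px, rep(0.5, nrow(back)))
})

test_that("overlays draw each status in its color and only when toggled", {
  ph <- small_phantom(seed = 13, n_border_pores = 1)
  s <- run_pass(pore_session(ph$image), pore_settings(denoise_strength = 0))
  has_color <- function(rgb, col) {
    hit <- rgb[, , 1] == col[1] & rgb[, , 2] == col[2] & rgb[, , 3] == col[3]
    any(hit)
  }
  ov <- render_overlay(s, display_settings(show_detected = TRUE,
                                           show_saved = FALSE,
                                           show_removed = FALSE))
  expect_true(has_color(ov, c(0, 255, 0)))      # green detected
  expect_false(has_color(ov, c(255, 0, 255)))   # no magenta
  expect_false(has_color(ov, c(255, 215, 0)))   # no gold
  ov2 <- render_overlay(s, display_settings(show_removed = TRUE))
  expect_true(has_color(ov2, c(255, 0, 255)))   # border pore in magenta
  s2 <- save_contour(s, 1)
  s2 <- remove_contour(s2, 2)
  ov3 <- render_overlay(s2, display_settings(show_removed = TRUE))
  expect_true(has_color(ov3, c(255, 215, 0)))   # gold saved
  expect_true(has_color(ov3, c(255, 165, 0)))   # orange user-removed
})

test_that("with every toggle off the overlay equals the underlay", {
  ph <- small_phantom(seed = 13)
  s <- run_pass(pore_session(ph$image), pore_settings(denoise_strength = 0))
  off <- display_settings(show_detected = FALSE, show_saved = FALSE,
                          show_removed = FALSE)
  ov <- render_overlay(s, off)
  expect_equal(ov[, , 1], ph$image + 0)
  expect_equal(ov[, , 2], ph$image + 0)
  expect_equal(ov[, , 3], ph$image + 0)
  # rendering does not mutate the session
  before <- glance(s)
  invisible(render_overlay(s, display_settings(show_numbers = TRUE,
                                               orientation_mode = "ellipse",
                                               show_removed = TRUE)))
  expect_identical(glance(s), before)
  expect_error(render_overlay(pore_session(ph$image)),
               class = "poremorph_state")
})

test_that("PNG save/load round-trips pixels exactly", {
  ph <- small_phantom(seed = 5)
  f <- withr::local_tempfile(fileext = ".png")
  save_png(ph$image, f)
  back <- load_image(f)
  expect_identical(back, ph$image)
  expect_error(load_image("no/such/file.png"), class = "poremorph_io")
  expect_error(save_png(ph$image, sub("png$", "bmp", f)),
               class = "poremorph_format")
})

test_that("16-bit TIFF input is rescaled to 8 bits with a warning", {
  f <- withr::local_tempfile(fileext = ".tif")
  m <- matrix(seq(0, 1, length.out = 64 * 64), 64, 64) * 0.7 + 0.1
  tiff::writeTIFF(m, f, bits.per.sample = 16)
  expect_warning(img <- load_image(f), "rescaled")
  expect_equal(range(img), c(0, 255)) # min-max mapping spans the full range
})

test_that("autoplot builds a status-colored ggplot", {
  ph <- small_phantom(seed = 13)
  s <- run_pass(pore_session(ph$image), pore_settings(denoise_strength = 0))
  p <- autoplot(s)
  expect_s3_class(p, "ggplot")
  built <- ggplot2::ggplot_build(p)
  expect_gt(nrow(built$data[[1]]), 0)
})
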