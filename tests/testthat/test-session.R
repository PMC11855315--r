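ph <- small_phantom(seed = 17)

test_that("passes number sequentially and leave the saved list untouched", {
  s <- pore_session(ph$image) |>
    run_pass(pore_settings(denoise_strength = 0))
  expect_equal(unique(s$detected$pass_id), 1L)
  expect_equal(nrow(s$detected), nrow(ph$truth))
  s <- save_contour(s, 2)
  n_saved <- nrow(s$saved)
  s2 <- run_pass(s, pore_settings(denoise_strength = 0, grayscale_threshold = 120))
  expect_equal(unique(s2$detected$pass_id), 2L)
  expect_equal(nrow(s2$saved), n_saved)
  expect_equal(s2$saved$pass_id, 1L)
})

test_that("an all-white image yields zero detections without error", {
  s <- run_pass(pore_session(matrix(255L, 64, 64)), pore_settings())
  expect_equal(nrow(s$detected), 0)
})

test_that("save and remove move single records and error on reuse", {
  s <- run_pass(pore_session(ph$image), pore_settings(denoise_strength = 0))
  n0 <- nrow(s$detected)
  s <- save_contour(s, 3)
  expect_equal(nrow(s$saved), 1)
  expect_equal(nrow(s$detected), n0 - 1)
  s <- remove_contour(s, 1)
  expect_equal(nrow(s$removed_user), 1)
  expect_equal(nrow(s$detected), n0 - 2)
  expect_error(remove_contour(s, 1), class = "poremorph_not_found")
  expect_error(save_contour(s, 3), class = "poremorph_not_found")
  expect_error(save_contour(s, 999), class = "poremorph_not_found")
})

test_that("range operations apply per id and silently skip absentees", {
  s <- run_pass(pore_session(ph$image), pore_settings(denoise_strength = 0))
  s <- remove_contour(s, 2)
  expect_message(s <- save_range(s, 1, 3), "skipping")
  expect_equal(sort(s$saved$pore_id), c(1L, 3L))
  expect_error(save_range(s, 5, 4), class = "poremorph_contract")
  # singleton range behaves like the single-id call
  s <- save_range(s, 4, 4)
  expect_true(4 %in% s$saved$pore_id)
})

test_that("per-pass conservation holds: detected + saved + removed = accepted", {
  s <- run_pass(pore_session(ph$image), pore_settings(denoise_strength = 0))
  acc <- nrow(s$detected)
  s <- save_range(s, 1, 2)
  s <- remove_contour(s, 4)
  expect_equal(nrow(s$detected) + nrow(s$saved) + nrow(s$removed_user), acc)
})

test_that("save profiles are immutable snapshots of their pass settings", {
  s <- run_pass(pore_session(ph$image),
                pore_settings(denoise_strength = 0, grayscale_threshold = 100))
  s <- save_contour(s, 1)
  s <- run_pass(s, pore_settings(denoise_strength = 0, grayscale_threshold = 140))
  s <- save_contour(s, 1)
  recs <- tidy(s, "saved")
  expect_equal(nrow(recs), 2)
  expect_equal(sort(recs$grayscale_threshold), c(100, 140))
  expect_equal(recs$pass_id, c(1L, 2L))
})

test_that("tidy and glance report the session state", {
  s <- run_pass(pore_session(ph$image), pore_settings(denoise_strength = 0))
  s <- save_contour(s, 1)
  g <- glance(s)
  expect_equal(g$n_passes, 1L)
  expect_equal(g$n_saved, 1L)
  td <- tidy(s, "detected")
  expect_true(all(c("pore_id", "area", "ipr", "grayscale_threshold",
                    "um_per_px") %in% names(td)))
})

test_that("overlap suppression drops re-detections of saved pores", {
  s <- run_pass(pore_session(ph$image), pore_settings(denoise_strength = 0))
  n0 <- nrow(s$detected)
  s <- save_range(s, 1, n0) # save everything
  s2 <- run_pass(s, pore_settings(denoise_strength = 0),
                 suppress_saved_overlap = TRUE)
  expect_equal(nrow(s2$detected), 0)
  s3 <- run_pass(s, pore_settings(denoise_strength = 0))
  expect_equal(nrow(s3$detected), n0) # off by default: duplicates kept
})

test_that("replaying a session script reproduces the CSV byte for byte", {
  script <- c(
    "# two-pass curation",
    "analyze denoise_strength=0 grayscale_threshold=100",
    "save 1",
    "saverange 2 3",
    "analyze denoise_strength=0 grayscale_threshold=130",
    "remove 1",
    "save 2"
  )
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  export_csv(replay_session(ph$image, script), "saved", f1)
  export_csv(replay_session(ph$image, script), "saved", f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  recs <- read_pore_csv(f1)
  expect_equal(sort(unique(recs$grayscale_threshold)), c(100, 130))
})

test_that("replay aborts with the offending line number", {
  err <- tryCatch(replay_session(ph$image, c("analyze denoise_strength=0",
                                             "save 99999")),
                  error = function(e) e)
  expect_s3_class(err, "poremorph_replay")
  expect_match(conditionMessage(err), "line 2")
})
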