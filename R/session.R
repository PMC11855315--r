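#' Start a pore-analysis session
#'
#' A session holds one image and accumulates analysis passes. Each pass runs
#' the full pipeline with its own settings; pores saved by the user persist
#' across passes, each carrying the settings bundle ("save profile") of the
#' pass that produced it. This mirrors the multi-pass workflow in which one
#' settings bundle outlines some pores well and others poorly, so the user
#' saves the good outlines and re-analyzes with new settings.
#'
#' @param image 8-bit grayscale matrix (see [load_image()]).
#' @return A `pore_session` object.
#' @export
pore_session <- function(image) {
  check_gray_image(image)
  structure(
    list(image = image,
         passes = list(),
         detected = empty_records(),
         saved = empty_records(),
         removed_user = empty_records()),
    class = "pore_session"
  )
}

empty_records <- function() {
  m <- measure_pores(tibble::tibble(vertices = list()),
                     matrix(FALSE, 1, 1), make_scale("pixel"))
  tibble::add_column(m, pass_id = integer(), .before = 1)
}

#' @export
print.pore_session <- function(x, ...) {
  cat(sprintf("<pore_session> %d x %d image, %d pass(es)\n",
              nrow(x$image), ncol(x$image), length(x$passes)))
  cat(sprintf("  detected (current pass): %d | saved: %d | removed by user: %d\n",
              nrow(x$detected), nrow(x$saved), nrow(x$removed_user)))
  invisible(x)
}

#' Run one analysis pass
#'
#' Executes preprocessing, contour detection, rejection and measurement with
#' the given settings; the accepted pores replace the currently detected set
#' (numbered from 1 within the pass), while previously saved pores are left
#' untouched. The settings bundle is recorded as the pass's save profile.
#'
#' @param session A [pore_session()].
#' @param settings A [pore_settings()] bundle.
#' @param suppress_saved_overlap If `TRUE`, newly accepted contours whose
#'   filled region overlaps an already saved contour with IoU > 0.5 are
#'   dropped from the detected set (the default mirrors the interactive tool,
#'   where the user curates duplicates by hand).
#' @return The updated session.
#' @export
run_pass <- function(session, settings, suppress_saved_overlap = FALSE) {
  stopifnot(inherits(session, "pore_session"), inherits(settings, "pore_settings"))
  pre <- preprocess_image(session$image, settings)
  det <- detect_pores(pre$binary, settings)
  meas <- measure_pores(det, pre$binary, settings$scale)
  if (suppress_saved_overlap && nrow(session$saved) && nrow(meas)) {
    dims <- dim(session$image)
    saved_masks <- lapply(session$saved$vertices, fill_polygon_cells, dims = dims)
    keep <- vapply(meas$vertices, function(v) {
      m <- fill_polygon_cells(v, dims)
      all(vapply(saved_masks, function(s) {
        length(intersect(m, s)) / length(union(m, s)) <= 0.5
      }, TRUE))
    }, TRUE)
    meas <- meas[keep, , drop = FALSE]
    meas$pore_id <- seq_len(nrow(meas))
  }
  pass_id <- length(session$passes) + 1L
  recs <- tibble::add_column(meas, pass_id = pass_id, .before = 1)
  session$passes[[pass_id]] <- list(pass_id = pass_id,
                                    settings = settings,
                                    detection = det,
                                    images = pre)
  session$detected <- recs
  session
}

current_settings <- function(session) {
  if (!length(session$passes))
    abort("no analysis pass has been run yet", class = "poremorph_state")
  session$passes[[length(session$passes)]]$settings
}

move_record <- function(session, pore_id, to) {
  idx <- match(pore_id, session$detected$pore_id)
  if (is.na(idx))
    abort(sprintf("pore %d is not in the currently detected set", pore_id),
          class = "poremorph_not_found")
  rec <- session$detected[idx, , drop = FALSE]
  session$detected <- session$detected[-idx, , drop = FALSE]
  session[[to]] <- dplyr::bind_rows(session[[to]], rec)
  session
}

#' Save or remove a single detected contour
#'
#' Saving moves the pore from the current pass's detected set into the saved
#' list, where it persists across later passes with its pass's save profile;
#' removing discards it as a user rejection. Either way the detected set
#' shrinks by one.
#'
#' @param session A [pore_session()] with at least one pass.
#' @param pore_id Pore number within the current pass (the red label).
#' @return The updated session.
#' @export
save_contour <- function(session, pore_id) move_record(session, pore_id, "saved")

#' @rdname save_contour
#' @export
remove_contour <- function(session, pore_id) move_record(session, pore_id, "removed_user")

range_op <- function(session, id_lo, id_hi, op) {
  if (id_lo > id_hi)
    abort("id_lo must not exceed id_hi", class = "poremorph_contract")
  ids <- seq.int(id_lo, id_hi)
  present <- ids[ids %in% session$detected$pore_id]
  skipped <- setdiff(ids, present)
  if (length(skipped))
    message("skipping ids not currently detected: ",
            paste(skipped, collapse = ", "))
  for (id in present) session <- op(session, id)
  session
}

#' Save or remove a range of contours
#'
#' Applies [save_contour()] / [remove_contour()] to every currently detected
#' pore id in `[id_lo, id_hi]`; ids in the range that are not detected are
#' skipped with a message.
#'
#' @inheritParams save_contour
#' @param id_lo,id_hi Inclusive id range, `id_lo <= id_hi`.
#' @return The updated session.
#' @export
save_range <- function(session, id_lo, id_hi)
  range_op(session, id_lo, id_hi, save_contour)

#' @rdname save_range
#' @export
remove_range <- function(session, id_lo, id_hi)
  range_op(session, id_lo, id_hi, remove_contour)

# settings of the pass that produced each record, as a one-row tibble each
profile_row <- function(settings) {
  tibble::tibble(
    min_pore_size_px = settings$min_pore_size_px,
    max_pore_size_px = settings$max_pore_size_px,
    denoise_strength = settings$denoise_strength,
    denoise_size = settings$denoise_size,
    grayscale_threshold = settings$grayscale_threshold,
    clahe_size = settings$clahe_size,
    clahe_clip_limit = settings$clahe_clip_limit,
    scale_mode = settings$scale$mode,
    um_per_px = settings$scale$um_per_px
  )
}

records_with_profiles <- function(session, which = c("detected", "saved")) {
  which <- match.arg(which)
  recs <- session[[which]]
  if (!nrow(recs)) return(recs)
  profs <- purrr::list_rbind(purrr::map(recs$pass_id,
    function(p) profile_row(session$passes[[p]]$settings)))
  dplyr::bind_cols(recs, profs)
}

#' Tidy a session into one pore per row
#'
#' @param x A [pore_session()].
#' @param which `"detected"` (current pass) or `"saved"`.
#' @param ... Unused.
#' @return Tibble of pore records with their save-profile columns.
#' @export
tidy.pore_session <- function(x, which = c("detected", "saved"), ...) {
  recs <- records_with_profiles(x, match.arg(which))
  recs$vertices <- NULL
  recs
}

#' One-row session summary
#'
#' @param x A [pore_session()].
#' @param ... Unused.
#' @return Tibble with pass, detection and curation counts.
#' @export
glance.pore_session <- function(x, ...) {
  tibble::tibble(
    n_passes = length(x$passes),
    n_detected = nrow(x$detected),
    n_saved = nrow(x$saved),
    n_removed_user = nrow(x$removed_user)
  )
}

#' Replay a recorded curation script
#'
#' Executes a plain-text command list against an image for byte-reproducible
#' curation. Commands, one per line (`#` comments allowed):
#' \describe{
#'   \item{`analyze key=value ...`}{run a pass; keys as in [read_settings()]}
#'   \item{`save N` / `remove N`}{curate a single pore}
#'   \item{`saverange A B` / `removerange A B`}{curate a range}
#'   \item{`export detected|saved PATH`}{write a CSV (see [export_csv()])}
#' }
#'
#' @param image 8-bit grayscale matrix.
#' @param script Path to the script file, or a character vector of lines.
#' @return The finished session, invisibly.
#' @export
replay_session <- function(image, script) {
  lines <- if (length(script) == 1 && file.exists(script))
    readLines(script, warn = FALSE) else script
  session <- pore_session(image)
  for (k in seq_along(lines)) {
    line <- trimws(sub("#.*$", "", lines[k]))
    if (!nzchar(line)) next
    tok <- strsplit(line, "\\s+")[[1]]
    res <- tryCatch(switch(tok[1],
      analyze = {
        settings <- if (length(tok) > 1)
          settings_from_pairs(tok[-1]) else pore_settings()
        run_pass(session, settings)
      },
      save = save_contour(session, as.integer(tok[2])),
      remove = remove_contour(session, as.integer(tok[2])),
      saverange = save_range(session, as.integer(tok[2]), as.integer(tok[3])),
      removerange = remove_range(session, as.integer(tok[2]), as.integer(tok[3])),
      export = {
        export_csv(session, which = tok[2], path = tok[3])
        session
      },
      abort(paste0("unknown command: ", tok[1]), class = "poremorph_contract")
    ), error = function(e) {
      abort(sprintf("replay failed at line %d: %s", k, conditionMessage(e)),
            class = "poremorph_replay")
    })
    session <- res
  }
  invisible(session)
}

# linear pixel indices (1-based) covered by a contour polygon, even-odd rule
# plus the boundary pixels themselves
fill_polygon_cells <- function(vertices, dims) {
  v <- as_vertex_matrix(vertices)
  x0 <- max(0, min(v[, 1])); x1 <- min(dims[2] - 1, max(v[, 1]))
  y0 <- max(0, min(v[, 2])); y1 <- min(dims[1] - 1, max(v[, 2]))
  gx <- rep(x0:x1, each = y1 - y0 + 1)
  gy <- rep(y0:y1, times = x1 - x0 + 1)
  inside <- point_in_polygon(gx, gy, v)
  cells <- (gx[inside]) * dims[1] + gy[inside] + 1
  union(cells, v[, 1] * dims[1] + v[, 2] + 1)
}

# even-odd ray-casting test, vectorized over query points
point_in_polygon <- function(px, py, v) {
  n <- nrow(v)
  xs <- v[, 1]; ys <- v[, 2]
  xe <- c(xs[-1], xs[1]); ye <- c(ys[-1], ys[1])
  inside <- rep(FALSE, length(px))
  for (k in seq_len(n)) {
    crosses <- ((ys[k] > py) != (ye[k] > py))
    if (any(crosses)) {
      xint <- xs[k] + (py[crosses] - ys[k]) / (ye[k] - ys[k]) * (xe[k] - xs[k])
      hit <- px[crosses] < xint
      inside[crosses] <- xor(inside[crosses], hit)
    }
  }
  inside
}

settings_from_pairs <- function(pairs) {
  tmp <- tempfile(fileext = ".cfg")
  on.exit(unlink(tmp))
  writeLines(pairs, tmp)
  read_settings(tmp)
}
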