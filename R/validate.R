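#' Percent deviation of a test value from a reference
#'
#' `|reference - test| / |reference| * 100`, the unsigned agreement metric
#' used to compare an automated measurement against a manual reference value
#' for the same pore.
#'
#' @param reference_value Reference (e.g. manual ImageJ) value, nonzero.
#' @param test_value Test (e.g. automated) value.
#' @return Percent deviation (vectorized).
#' @examples
#' percent_deviation(1271, 1000) # 21.3 (1 d.p.)
#' @export
percent_deviation <- function(reference_value, test_value) {
  if (any(reference_value == 0))
    abort("percent deviation is undefined for a zero reference",
          class = "poremorph_undefined_deviation")
  abs(reference_value - test_value) / abs(reference_value) * 100
}

#' Signed percent difference of a test value from a reference
#'
#' `(test - reference) / reference * 100`, sign preserved, for group-level
#' method comparisons.
#'
#' @inheritParams percent_deviation
#' @return Signed percent difference (vectorized).
#' @export
signed_percent_difference <- function(reference_value, test_value) {
  if (any(reference_value == 0))
    abort("percent difference is undefined for a zero reference",
          class = "poremorph_undefined_deviation")
  (test_value - reference_value) / reference_value * 100
}

#' Summarize one method's measurements across researchers
#'
#' Each researcher (or replicate) contributes a vector of per-pore
#' measurements. The group summary reports, per parameter: the mean of the
#' per-user averages, the sample standard deviation of those averages
#' (between-user variability), and the mean of the per-user sample standard
#' deviations (within-user variability).
#'
#' @param measurements A long tibble with columns `user`, `parameter`,
#'   `value`, or (for a single parameter) a named list of numeric vectors,
#'   one per user.
#' @return A tibble, one row per parameter: `parameter`, `n_users`,
#'   `mean_of_averages`, `std_of_averages` (`NA` with one user),
#'   `mean_of_stds` (single-measurement users contribute 0, flagged by
#'   `degenerate_users > 0`).
#' @examples
#' summarize_group(list(u1 = c(1, 2, 3), u2 = c(2, 3, 4)))
#' @export
summarize_group <- function(measurements) {
  df <- if (is.data.frame(measurements)) {
    stopifnot(all(c("user", "value") %in% names(measurements)))
    m <- measurements
    if (!"parameter" %in% names(m)) m$parameter <- "value"
    m
  } else {
    if (!length(measurements) || any(!lengths(measurements)))
      abort("each user needs at least one measurement", class = "poremorph_contract")
    users <- names(measurements)
    if (is.null(users)) users <- paste0("user", seq_along(measurements))
    tibble::tibble(
      user = rep(users, lengths(measurements)),
      parameter = "value",
      value = unlist(measurements, use.names = FALSE)
    )
  }
  per_user <- df |>
    dplyr::group_by(.data$parameter, .data$user) |>
    dplyr::summarize(m = mean(.data$value),
                     s = if (dplyr::n() > 1) sd(.data$value) else 0,
                     deg = dplyr::n() < 2, .groups = "drop")
  per_user |>
    dplyr::group_by(.data$parameter) |>
    dplyr::summarize(
      n_users = dplyr::n(),
      mean_of_averages = mean(.data$m),
      std_of_averages = if (dplyr::n() > 1) sd(.data$m) else NA_real_,
      mean_of_stds = mean(.data$s),
      degenerate_users = sum(.data$deg),
      .groups = "drop"
    )
}

#' Compare two method summaries parameter by parameter
#'
#' Given [summarize_group()] results for a reference method and a test
#' method, emits a long comparison table: the three summary columns for each
#' method and the signed percent difference of each column, test relative to
#' reference.
#'
#' @param reference,test Tibbles from [summarize_group()] over the same
#'   parameter set (e.g. manual ImageJ vs the automated pipeline).
#' @return A tibble with one row per parameter x summary-statistic:
#'   `parameter`, `statistic`, `reference`, `test`, `pct_difference`.
#' @export
compare_methods <- function(reference, test) {
  if (!setequal(reference$parameter, test$parameter))
    abort("reference and test must cover the same parameters",
          class = "poremorph_contract")
  stats <- c("mean_of_averages", "std_of_averages", "mean_of_stds")
  long <- function(x, nm) {
    x |>
      dplyr::select(dplyr::all_of(c("parameter", stats))) |>
      tidyr::pivot_longer(dplyr::all_of(stats), names_to = "statistic",
                          values_to = nm)
  }
  dplyr::inner_join(long(reference, "reference"), long(test, "test"),
                    by = c("parameter", "statistic")) |>
    dplyr::mutate(pct_difference =
                    signed_percent_difference(.data$reference, .data$test))
}

#' Round half-even to one decimal, as printed in comparison tables
#'
#' @param x Numeric vector.
#' @return `x` rounded to 1 decimal place (banker's rounding).
#' @export
round1 <- function(x) round(x, 1)

#' Bundled method-comparison datasets
#'
#' Two small validation datasets comparing manual freehand ImageJ
#' measurements against this pipeline's automated measurements on the same
#' cryogel SEM image:
#'
#' * `tool_comparison_pores()`: ten individual pores measured both ways
#'   (columns: `pore`, then `area_um2`, `perimeter_um`, `orientation_deg`
#'   for each of `automated` and `imagej`), for per-pore percent-deviation
#'   arithmetic.
#' * `tool_comparison_groups()`: group-level summaries from five first-time
#'   users per method (columns: `method`, `parameter`, `mean_of_averages`,
#'   `std_of_averages`, `mean_of_stds`), for signed percent-difference
#'   arithmetic. Areas in um^2, perimeters in um, orientations in degrees,
#'   time in minutes.
#'
#' @return A tibble (see above).
#' @export
tool_comparison_pores <- function() {
  readr::read_csv(system.file("extdata", "tool_comparison_pores.csv",
                              package = "poremorph"),
                  show_col_types = FALSE)
}

#' @rdname tool_comparison_pores
#' @export
tool_comparison_groups <- function() {
  readr::read_csv(system.file("extdata", "tool_comparison_groups.csv",
                              package = "poremorph"),
                  show_col_types = FALSE)
}
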