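#' Median absolute deviation of well values
#'
#' The median of absolute deviations from the median. Unscaled by default —
#' the robust z-score divides by the plain MAD — with the Gaussian
#' consistency factor 1.4826 available behind a flag.
#'
#' @param values Numeric vector, non-empty and finite.
#' @param scaled Multiply by 1.4826 (default `FALSE`).
#' @return The (optionally scaled) MAD.
#' @export
#' @examples
#' screen_mad(c(1, 2, 3, 4, 5))  # 1
screen_mad <- function(values, scaled = FALSE) {
  if (length(values) == 0) {
    stop_hcs("Cannot compute the MAD of an empty vector.", "parameter_error")
  }
  if (any(!is.finite(values))) {
    stop_hcs("MAD input must be finite.", "parameter_error")
  }
  m <- median(abs(values - median(values)))
  if (scaled) m * 1.4826 else m
}

#' Robust z-scores for one plate
#'
#' Standardizes each well's value against its plate:
#' `z = (value - plate_median) / plate_MAD`, where the median and MAD are
#' computed over the plate's contributing wells. By default only valid
#' sample wells contribute to the plate statistics; control wells can be
#' included via `include_controls`. Background wells and invalid
#' (low-cell-count) wells never contribute. Non-contributing wells still
#' receive a z-score computed against the plate statistics, flagged by
#' `contributing = FALSE`.
#'
#' @param wells Tibble with a `value` column; optional columns `content`
#'   and `valid` refine which wells contribute (all wells contribute when
#'   absent), and `plate_id`/`well_id`/`sirna_id`/`gene_id` are carried
#'   through.
#' @param include_controls Let negative/positive control wells contribute to
#'   the plate median and MAD (default `FALSE`).
#' @param mad_scaled Use the 1.4826-scaled MAD (default `FALSE`, the plain
#'   ratio).
#' @param min_wells Minimum number of contributing wells (default 8).
#' @return `wells` with `z`, `plate_median`, `plate_mad` and `contributing`
#'   columns added.
#' @export
#' @examples
#' robust_zscore_plate(tibble::tibble(value = c(1, 2, 3, 4, 5)))$z
robust_zscore_plate <- function(wells, include_controls = FALSE,
                                mad_scaled = FALSE, min_wells = 8) {
  if (!"value" %in% names(wells)) {
    stop_hcs("`wells` must have a `value` column.", "data_error")
  }
  plate <- if ("plate_id" %in% names(wells)) wells$plate_id[1] else "<plate>"
  contributing <- !is.na(wells$value)
  if ("valid" %in% names(wells)) {
    contributing <- contributing & wells$valid
  }
  if ("content" %in% names(wells)) {
    ok <- wells$content == "sample" |
      (include_controls &
         wells$content %in% c("negative_control", "positive_control"))
    contributing <- contributing & ok
  }
  vals <- wells$value[contributing]
  if (length(vals) < min_wells) {
    stop_hcs(sprintf(
      "Plate %s has %d contributing wells; at least %d are required.",
      plate, length(vals), min_wells), "data_error")
  }
  med <- median(vals)
  mad_val <- screen_mad(vals, scaled = mad_scaled)
  if (mad_val == 0) {
    stop_hcs(sprintf("Plate %s is degenerate: MAD of contributing wells is 0.",
                     plate), "degenerate_plate")
  }
  wells$z <- (wells$value - med) / mad_val
  wells$plate_median <- med
  wells$plate_mad <- mad_val
  wells$contributing <- contributing
  wells
}

#' Robust z-scores for a whole screen
#'
#' Applies [robust_zscore_plate()] plate by plate, standardizing every well
#' against its own plate's median and MAD so that plate-to-plate variation
#' drops out.
#'
#' @param wells Well tibble with `plate_id` and the value column named by
#'   `value_col` (default `"corrected_value"`, the background-corrected
#'   per-well mean); other columns as in [robust_zscore_plate()].
#' @param value_col Name of the column holding the per-well value to
#'   normalize.
#' @inheritParams robust_zscore_plate
#' @return One `ZScoreRecord` row per well: input columns plus `value`, `z`,
#'   `plate_median`, `plate_mad`, `contributing`.
#' @export
robust_zscore <- function(wells, value_col = "corrected_value",
                          include_controls = FALSE, mad_scaled = FALSE,
                          min_wells = 8) {
  if (!value_col %in% names(wells)) {
    stop_hcs(sprintf("`wells` has no column `%s`.", value_col), "data_error")
  }
  wells$value <- wells[[value_col]]
  parts <- split(wells, wells$plate_id)
  bind_rows(lapply(parts, robust_zscore_plate,
                   include_controls = include_controls,
                   mad_scaled = mad_scaled, min_wells = min_wells))
}
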