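#' Run the full variability analysis
#'
#' One-call pipeline mirroring the tool's control panel: convert the
#' series to mg/dL, align it to the sampling grid, optionally restrict to
#' an analysis window, fill bounded gaps by linear interpolation, and
#' compute every metric: Avg. AUC-H/L, PATR/PBTR, SD, CONGA(n), MODD and
#' MAGE (+/-/avg., excursion frequency, visual-analysis alert).
#'
#' Undefined metrics (e.g. MODD on a recording of 24 h or less, MAGE on a
#' curve without meaningful excursions) are reported as `NA` and
#' serialized as `null` by [write_report()] — never fabricated as 0.
#' When the retained MAGE curve still contains a sub-threshold excursion,
#' the alert flag is set and the message
#' `"Visual analysis should be performed, see User Documentation"` is
#' emitted.
#'
#' @param series a [glucose_series()] (any unit; converted to mg/dL).
#' @param range a [target_range()] in mg/dL (user-set; no universal
#'   default exists).
#' @param me meaningful-excursion threshold for MAGE, mg/dL (default 45).
#' @param conga_n CONGA lag in hours (default 1).
#' @param interval grid spacing, minutes (default the series' nominal
#'   interval).
#' @param max_gap interpolation cap: longest missing run (slots) that may
#'   be filled (default 21).
#' @param window_start,window_hours optional analysis window (UTC start +
#'   length in hours); default: the full recording.
#' @return An object of class `variability_report`; see [write_report()]
#'   for the serialized fields.
#' @examples
#' s <- generate_series(fixture_spec("sinusoid", duration_hours = 48,
#'                                   baseline = 120, amplitude = 40))
#' run_analysis(s, target_range(80, 150))
#' @export
run_analysis <- function(series, range, me = 45, conga_n = 1,
                         interval = series$nominal_interval, max_gap = 21,
                         window_start = NULL, window_hours = NULL) {
  stopifnot(inherits(series, "glucose_series"),
            inherits(range, "target_range"))
  if (me <= 0) {
    stop("meaningful-excursion threshold must be positive", call. = FALSE)
  }

  series <- convert_units(series, "mg_dL")
  gridded <- align_to_grid(series, interval = interval)
  if (!is.null(window_start) || !is.null(window_hours)) {
    if (is.null(window_start)) {
      window_start <- gridded$start
    }
    if (is.null(window_hours)) {
      stop("window_hours must be given with window_start", call. = FALSE)
    }
    gridded <- select_window(gridded, window_start, window_hours * 60)
  }
  gridded <- interpolate_gaps(gridded, max_gap = max_gap)

  tir <- time_in_ranges(gridded, range)
  mage <- compute_mage(gridded, me = me)

  report <- structure(
    list(
      avg_auc_high = avg_auc_high(gridded, range$tr_high),
      avg_auc_low = avg_auc_low(gridded, range$tr_low),
      patr = tir$patr,
      pbtr = tir$pbtr,
      in_range = tir$in_range,
      sd = glucose_sd(gridded),
      conga = conga(gridded, n = conga_n),
      conga_n = conga_n,
      modd = modd(gridded),
      mage_plus = mage$mage_plus,
      mage_minus = mage$mage_minus,
      mage_avg = mage$mage_avg,
      excursion_frequency = mage$excursion_frequency,
      n_total_points = n_observed(gridded),
      n_interpolated_points = n_interpolated(gridded),
      alert_visual_analysis = mage$alert_visual_analysis,
      retained_points = mage$retained_points,
      target_range = range,
      me = me,
      window_start = gridded$start,
      window_minutes = length(gridded$glucose) * gridded$interval,
      gridded = gridded
    ),
    class = "variability_report"
  )
  if (isTRUE(mage$alert_visual_analysis)) {
    message("Visual analysis should be performed, see User Documentation")
  }
  report
}

#' @export
print.variability_report <- function(x, ...) {
  fmt <- function(v, unit = "mg/dL") {
    if (is.null(v) || is.na(v)) "undefined" else sprintf("%.2f %s", v, unit)
  }
  cat("<variability_report>\n")
  cat(sprintf("  window: %s + %g min, target range %g-%g mg/dL, ME %g mg/dL\n",
              format(x$window_start, tz = "UTC"), x$window_minutes,
              x$target_range$tr_low, x$target_range$tr_high, x$me))
  cat(sprintf("  points: %d observed (%d interpolated)\n",
              x$n_total_points, x$n_interpolated_points))
  cat("  Avg. AUC-H:", fmt(x$avg_auc_high), " Avg. AUC-L:", fmt(x$avg_auc_low), "\n")
  cat("  PATR:", fmt(x$patr, "%"), " PBTR:", fmt(x$pbtr, "%"), "\n")
  cat("  SD:", fmt(x$sd), sprintf(" CONGA(%g):", x$conga_n), fmt(x$conga),
      " MODD:", fmt(x$modd), "\n")
  cat("  MAGE+:", fmt(x$mage_plus), " MAGE-:", fmt(x$mage_minus),
      " MAGE avg.:", fmt(x$mage_avg), "\n")
  cat("  excursion frequency:", x$excursion_frequency, "\n")
  if (isTRUE(x$alert_visual_analysis)) {
    cat("  Visual analysis should be performed, see User Documentation\n")
  }
  invisible(x)
}
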