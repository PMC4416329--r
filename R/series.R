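#' @keywords internal
"_PACKAGE"

# mg/dL per mmol/L: molar mass of glucose 180.182 g/mol divided by 10.
MGDL_PER_MMOL <- 18.0182

VALID_UNITS <- c("mg_dL", "mmol_L")

#' Construct a glucose series
#'
#' A `glucose_series` holds timestamped glucose readings in a declared unit.
#' It is the raw-input container produced by the readers and by
#' [generate_series()], and the input to [align_to_grid()].
#'
#' @param timestamp `POSIXct` vector (or something coercible via
#'   [as.POSIXct()] with `tz = "UTC"`), minute resolution or finer.
#' @param glucose numeric vector of glucose concentrations, same length as
#'   `timestamp`; all values must be finite and positive.
#' @param unit `"mg_dL"` or `"mmol_L"`.
#' @param patient_id opaque label attached to the series.
#' @param nominal_interval nominal sampling interval in minutes (default 5,
#'   the usual CGM rate).
#' @param source_flag per-sample provenance, `"measured"` (default) or
#'   `"interpolated"`; recycled if length 1.
#'
#' @return An object of class `glucose_series`: a list with elements
#'   `samples` (data frame with columns `timestamp`, `glucose`,
#'   `source_flag`, sorted by timestamp), `unit`, `patient_id` and
#'   `nominal_interval`.
#'
#' @details Samples are sorted by timestamp. Duplicate timestamps carrying
#'   identical glucose values are silently deduplicated; duplicates with
#'   conflicting glucose values are an error.
#'
#' @examples
#' ts <- as.POSIXct("2024-01-01 00:00", tz = "UTC") + 300 * (0:2)
#' glucose_series(ts, c(100, 110, 120), unit = "mg_dL")
#' @export
glucose_series <- function(timestamp, glucose, unit = "mg_dL",
                           patient_id = NA_character_,
                           nominal_interval = 5,
                           source_flag = "measured") {
  if (!inherits(timestamp, "POSIXct")) {
    timestamp <- as.POSIXct(timestamp, tz = "UTC")
  }
  glucose <- as.numeric(glucose)
  if (length(timestamp) != length(glucose)) {
    stop("`timestamp` and `glucose` must have the same length", call. = FALSE)
  }
  if (anyNA(timestamp)) {
    stop("timestamps contain unparseable or missing values", call. = FALSE)
  }
  if (any(!is.finite(glucose)) || any(glucose <= 0)) {
    stop("glucose values must be finite and > 0", call. = FALSE)
  }
  unit <- match.arg(unit, VALID_UNITS)
  source_flag <- rep_len(as.character(source_flag), length(glucose))
  if (!all(source_flag %in% c("measured", "interpolated"))) {
    stop("source_flag must be 'measured' or 'interpolated'", call. = FALSE)
  }

  ord <- order(timestamp)
  samples <- data.frame(
    timestamp = timestamp[ord],
    glucose = glucose[ord],
    source_flag = source_flag[ord],
    stringsAsFactors = FALSE
  )

  dup <- duplicated(samples$timestamp)
  if (any(dup)) {
    # identical duplicates are dropped; conflicting ones are a data error
    for (t in unique(samples$timestamp[dup])) {
      g <- samples$glucose[samples$timestamp == t]
      if (length(unique(g)) > 1L) {
        stop(sprintf(
          "conflicting glucose values (%s) at duplicate timestamp %s",
          paste(unique(g), collapse = ", "), format(t, tz = "UTC")
        ), call. = FALSE)
      }
    }
    samples <- samples[!dup, , drop = FALSE]
    rownames(samples) <- NULL
  }

  structure(
    list(
      samples = samples,
      unit = unit,
      patient_id = patient_id,
      nominal_interval = nominal_interval
    ),
    class = "glucose_series"
  )
}

#' @export
print.glucose_series <- function(x, ...) {
  n <- nrow(x$samples)
  cat(sprintf(
    "<glucose_series> %d samples [%s], unit %s, nominal interval %g min\n",
    n,
    if (n > 0) {
      paste(format(range(x$samples$timestamp), tz = "UTC"), collapse = " .. ")
    } else "empty",
    x$unit, x$nominal_interval
  ))
  invisible(x)
}

#' @export
length.glucose_series <- function(x) nrow(x$samples)

#' Convert a glucose series between mg/dL and mmol/L
#'
#' Uses the fixed factor 18.0182 mg/dL per mmol/L (molar mass of glucose
#' 180.182 g/mol / 10). Conversion is exact up to floating precision; no
#' rounding is applied.
#'
#' @param series a [glucose_series()].
#' @param target `"mg_dL"` or `"mmol_L"`.
#' @return The series expressed in `target` units. If `target` equals the
#'   current unit the series is returned unchanged.
#' @examples
#' s <- glucose_series(as.POSIXct("2024-01-01", tz = "UTC"), 5, unit = "mmol_L")
#' convert_units(s, "mg_dL")$samples$glucose  # 90.091
#' @export
convert_units <- function(series, target) {
  stopifnot(inherits(series, "glucose_series"))
  target <- match.arg(target, VALID_UNITS)
  if (identical(series$unit, target)) {
    return(series)
  }
  f <- if (target == "mg_dL") MGDL_PER_MMOL else 1 / MGDL_PER_MMOL
  series$samples$glucose <- series$samples$glucose * f
  series$unit <- target
  series
}

#' Define a glycemic target range
#'
#' The lower and upper glycemic thresholds (TR_L, TR_H) in mg/dL against
#' which the exposure metrics (Avg. AUC-H/L) and the time-in-range
#' percentages (PATR/PBTR) are computed. The range is user-set: no
#' universal clinical default exists.
#'
#' @param tr_low,tr_high lower/upper bound, mg/dL; `0 < tr_low < tr_high`.
#' @return An object of class `target_range`.
#' @examples
#' target_range(80, 150)
#' @export
target_range <- function(tr_low, tr_high) {
  tr_low <- as.numeric(tr_low)
  tr_high <- as.numeric(tr_high)
  if (!is.finite(tr_low) || !is.finite(tr_high) ||
      tr_low <= 0 || tr_low >= tr_high) {
    stop("target range requires 0 < tr_low < tr_high", call. = FALSE)
  }
  structure(list(tr_low = tr_low, tr_high = tr_high), class = "target_range")
}

#' @export
print.target_range <- function(x, ...) {
  cat(sprintf("<target_range> %g - %g mg/dL\n", x$tr_low, x$tr_high))
  invisible(x)
}
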