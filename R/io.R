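# Timestamp parsing: ISO-8601 (default) or day-first European exports.
parse_timestamps <- function(x, dialect = c("iso8601", "dmy")) {
  dialect <- match.arg(dialect)
  x <- trimws(as.character(x))
  fmts <- switch(dialect,
    iso8601 = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S",
                "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M", "%Y-%m-%d"),
    dmy = c("%d/%m/%Y %H:%M:%S", "%d/%m/%Y %H:%M", "%d/%m/%Y")
  )
  out <- as.POSIXct(rep(NA_real_, length(x)), origin = "1970-01-01",
                    tz = "UTC")
  for (f in fmts) {
    todo <- is.na(out) & nzchar(x)
    if (!any(todo)) break
    out[todo] <- as.POSIXct(x[todo], tz = "UTC", format = f)
  }
  out
}

#' Read a generic two-column CGM export
#'
#' Reads a delimited text file holding one timestamp column and one glucose
#' column (any other columns are ignored) into a [glucose_series()]. Rows
#' whose glucose cell is empty are dropped; they surface later as grid gaps.
#'
#' @param path file path of a CSV (or other single-character-delimited) file.
#' @param timestamp_column,glucose_column column names.
#' @param unit unit of the glucose column, `"mg_dL"` or `"mmol_L"`.
#' @param dialect timestamp dialect: `"iso8601"` (default) or `"dmy"`
#'   (`DD/MM/YYYY HH:MM`).
#' @param sep field separator (default `","`).
#' @param patient_id optional label stored on the series.
#' @return A sorted, deduplicated [glucose_series()].
#' @seealso [read_carelink_export()] for CareLink-style exports.
#' @export
read_generic_csv <- function(path, timestamp_column = "timestamp",
                             glucose_column = "glucose",
                             unit = "mg_dL",
                             dialect = c("iso8601", "dmy"),
                             sep = ",",
                             patient_id = NA_character_) {
  if (!file.exists(path)) {
    stop(sprintf("input file not found: %s", path), call. = FALSE)
  }
  dialect <- match.arg(dialect)
  df <- utils::read.csv(path, sep = sep, stringsAsFactors = FALSE,
                        check.names = FALSE, colClasses = "character")
  for (col in c(timestamp_column, glucose_column)) {
    if (!col %in% names(df)) {
      stop(sprintf("column '%s' not found in %s (headers: %s)",
                   col, path, paste(names(df), collapse = ", ")),
           call. = FALSE)
    }
  }
  raw_ts <- df[[timestamp_column]]
  raw_g <- trimws(df[[glucose_column]])
  keep <- nzchar(raw_g) & !is.na(raw_g)   # empty glucose cells -> grid gaps
  raw_ts <- raw_ts[keep]
  raw_g <- raw_g[keep]
  if (length(raw_g) == 0L) {
    stop("no glucose rows found in input", call. = FALSE)
  }
  ts <- parse_timestamps(raw_ts, dialect)
  if (anyNA(ts)) {
    bad <- which(is.na(ts))[1L]
    stop(sprintf("unparseable timestamp '%s' at data row %d",
                 raw_ts[bad], which(keep)[bad]), call. = FALSE)
  }
  g <- suppressWarnings(as.numeric(raw_g))
  if (anyNA(g)) {
    bad <- which(is.na(g))[1L]
    stop(sprintf("non-numeric glucose '%s' at data row %d",
                 raw_g[bad], which(keep)[bad]), call. = FALSE)
  }
  glucose_series(ts, g, unit = unit, patient_id = patient_id)
}

# Recognized sensor-glucose headers, most specific first.
CARELINK_GLUCOSE_ALIASES <- list(
  list(name = "Sensor Glucose (mg/dL)", unit = "mg_dL"),
  list(name = "Sensor Glucose (mmol/L)", unit = "mmol_L"),
  list(name = "Sensor Glucose", unit = "mg_dL")
)

#' Read a CareLink-style CGM export
#'
#' Reads a delimited re-export of a CareLink Professional/Personal file:
#' a table with a timestamp field (either a `Timestamp` column or separate
#' `Date` + `Time` columns) and a sensor-glucose column among many others.
#' Rows without a sensor-glucose value (calibration entries, alarms, meter
#' readings) are skipped. The glucose unit is taken from the recognized
#' header (`Sensor Glucose (mg/dL)` or `(mmol/L)`).
#'
#' Binary `.xls` files are not parsed; re-export the sheet as CSV.
#'
#' @param path file path of the delimited export.
#' @param dialect timestamp dialect, `"iso8601"` or `"dmy"`.
#' @param sep field separator (default `","`).
#' @param patient_id optional label stored on the series.
#' @return A [glucose_series()] in the unit declared by the export header.
#' @export
read_carelink_export <- function(path, dialect = c("iso8601", "dmy"),
                                 sep = ",", patient_id = NA_character_) {
  if (!file.exists(path)) {
    stop(sprintf("input file not found: %s", path), call. = FALSE)
  }
  dialect <- match.arg(dialect)
  df <- utils::read.csv(path, sep = sep, stringsAsFactors = FALSE,
                        check.names = FALSE, colClasses = "character")
  hdr <- names(df)

  gcol <- NULL
  unit <- NULL
  for (alias in CARELINK_GLUCOSE_ALIASES) {
    if (alias$name %in% hdr) {
      gcol <- alias$name
      unit <- alias$unit
      break
    }
  }
  if (is.null(gcol)) {
    stop(sprintf("no sensor glucose column recognized; detected headers: %s",
                 paste(hdr, collapse = ", ")), call. = FALSE)
  }

  if ("Timestamp" %in% hdr) {
    raw_ts <- df[["Timestamp"]]
  } else if (all(c("Date", "Time") %in% hdr)) {
    raw_ts <- paste(df[["Date"]], df[["Time"]])
  } else {
    stop(sprintf("no timestamp column recognized; detected headers: %s",
                 paste(hdr, collapse = ", ")), call. = FALSE)
  }

  raw_g <- trimws(df[[gcol]])
  keep <- nzchar(raw_g) & !is.na(raw_g)
  if (!any(keep)) {
    stop("no sensor glucose rows", call. = FALSE)
  }
  ts <- parse_timestamps(raw_ts[keep], dialect)
  if (anyNA(ts)) {
    bad <- which(is.na(ts))[1L]
    stop(sprintf("unparseable timestamp '%s' at data row %d",
                 raw_ts[keep][bad], which(keep)[bad]), call. = FALSE)
  }
  g <- suppressWarnings(as.numeric(raw_g[keep]))
  if (anyNA(g)) {
    stop("non-numeric sensor glucose value in export", call. = FALSE)
  }
  glucose_series(ts, g, unit = unit, patient_id = patient_id)
}

#' Write a glucose series as generic CSV
#'
#' Inverse of [read_generic_csv()]: writes `timestamp` (ISO-8601, UTC) and
#' `glucose` columns so that reading the file back reproduces the series.
#'
#' @param series a [glucose_series()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_generic_csv <- function(series, path) {
  stopifnot(inherits(series, "glucose_series"))
  df <- data.frame(
    timestamp = format(series$samples$timestamp, "%Y-%m-%dT%H:%M:%S",
                       tz = "UTC"),
    glucose = series$samples$glucose
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a variability report to disk
#'
#' Serializes a [run_analysis()] report as JSON (stable, documented keys;
#' undefined metrics written as explicit `null`, never as 0) or as a
#' single-row CSV (undefined metrics as empty cells).
#'
#' @param report a `variability_report` as returned by [run_analysis()].
#' @param path output file path.
#' @param format `"json"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, format = c("json", "csv")) {
  stopifnot(inherits(report, "variability_report"))
  format <- match.arg(format)
  flat <- report_fields(report)
  if (format == "json") {
    jsonlite::write_json(flat, path, auto_unbox = TRUE, digits = NA,
                         null = "null", pretty = TRUE)
  } else {
    row <- lapply(flat, function(v) {
      if (is.null(v) || length(v) == 0L) NA else v
    })
    utils::write.csv(as.data.frame(row, stringsAsFactors = FALSE), path,
                     row.names = FALSE, na = "")
  }
  invisible(path)
}

# Flatten a report into an ordered named list; NA metric -> NULL (JSON null).
report_fields <- function(report) {
  num_or_null <- function(v) {
    if (is.null(v) || length(v) == 0L || is.na(v)) NULL else unname(v)
  }
  list(
    avg_auc_high = num_or_null(report$avg_auc_high),
    avg_auc_low = num_or_null(report$avg_auc_low),
    patr = num_or_null(report$patr),
    pbtr = num_or_null(report$pbtr),
    in_range = num_or_null(report$in_range),
    sd = num_or_null(report$sd),
    conga = num_or_null(report$conga),
    conga_n = report$conga_n,
    modd = num_or_null(report$modd),
    mage_plus = num_or_null(report$mage_plus),
    mage_minus = num_or_null(report$mage_minus),
    mage_avg = num_or_null(report$mage_avg),
    excursion_frequency = report$excursion_frequency,
    n_total_points = report$n_total_points,
    n_interpolated_points = report$n_interpolated_points,
    alert_visual_analysis = report$alert_visual_analysis,
    tr_low = report$target_range$tr_low,
    tr_high = report$target_range$tr_high,
    me = report$me,
    window_start = format(report$window_start, "%Y-%m-%dT%H:%M:%S",
                          tz = "UTC"),
    window_minutes = report$window_minutes,
    unit = "mg_dL"
  )
}
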