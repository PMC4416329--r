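#' Gridded glucose series
#'
#' Internal constructor for the fixed-grid representation: slot `k`
#' (1-based) corresponds to time `start + (k - 1) * interval` minutes.
#' Missing slots carry `NA` glucose and flag `"missing"`.
#'
#' @param start `POSIXct` time of the first slot.
#' @param interval slot spacing, minutes.
#' @param glucose numeric vector, `NA` where missing.
#' @param flag character vector: `"measured"`, `"interpolated"` or
#'   `"missing"`; must be `"missing"` exactly where glucose is `NA`.
#' @return An object of class `gridded_series`.
#' @export
new_gridded_series <- function(start, interval, glucose, flag) {
  stopifnot(length(glucose) == length(flag))
  if (any(is.na(glucose) != (flag == "missing"))) {
    stop("flag must be 'missing' exactly where glucose is NA", call. = FALSE)
  }
  structure(
    list(start = start, interval = interval,
         glucose = as.numeric(glucose), flag = flag),
    class = "gridded_series"
  )
}

#' @export
print.gridded_series <- function(x, ...) {
  cat(sprintf(
    "<gridded_series> %d slots @ %g min from %s (%d measured, %d interpolated, %d missing)\n",
    length(x$glucose), x$interval, format(x$start, tz = "UTC"),
    n_measured(x), n_interpolated(x), sum(x$flag == "missing")
  ))
  invisible(x)
}

#' @export
length.gridded_series <- function(x) length(x$glucose)

#' Slot bookkeeping of a gridded series
#'
#' `n_measured()` and `n_interpolated()` count slots by provenance;
#' `n_observed()` is their sum (slots carrying a glucose value);
#' `slot_times()` returns the `POSIXct` time of every slot.
#'
#' @param gridded a `gridded_series`.
#' @return An integer count, or for `slot_times()` a `POSIXct` vector.
#' @export
n_measured <- function(gridded) sum(gridded$flag == "measured")

#' @rdname n_measured
#' @export
n_interpolated <- function(gridded) sum(gridded$flag == "interpolated")

#' @rdname n_measured
#' @export
n_observed <- function(gridded) sum(gridded$flag != "missing")

#' @rdname n_measured
#' @export
slot_times <- function(gridded) {
  gridded$start + 60 * gridded$interval * (seq_along(gridded$glucose) - 1)
}

#' Align a glucose series to a fixed sampling grid
#'
#' Assigns each sample to its nearest grid slot. The grid anchor is the
#' first sample's timestamp rounded down to a whole multiple of `interval`
#' minutes (deterministic, and matching the fixed epochs of CGM devices);
#' the grid extends to the slot of the last sample. Slots receiving no
#' sample are marked missing. Two samples falling in one slot indicate
#' ambiguous (super-nominal) sampling and are an error.
#'
#' @param series a [glucose_series()].
#' @param interval grid spacing in minutes; defaults to the series'
#'   nominal interval (5 min for the usual CGM rate).
#' @return A `gridded_series`.
#' @examples
#' ts <- as.POSIXct("2024-01-01 00:00", tz = "UTC") + 300 * (0:3)
#' g <- align_to_grid(glucose_series(ts, c(100, 105, 110, 115)))
#' n_observed(g)
#' @export
align_to_grid <- function(series, interval = series$nominal_interval) {
  stopifnot(inherits(series, "glucose_series"))
  if (nrow(series$samples) == 0L) {
    stop("cannot grid an empty series", call. = FALSE)
  }
  step <- 60 * interval
  t0 <- as.numeric(series$samples$timestamp[1L])
  anchor <- floor(t0 / step) * step
  # nearest slot; ties at exactly interval/2 round up (deterministic)
  offs <- as.numeric(series$samples$timestamp) - anchor
  slot <- as.integer(floor(offs / step + 0.5)) + 1L
  if (anyDuplicated(slot)) {
    k <- slot[which(duplicated(slot))[1L]]
    stop(sprintf(
      "two samples map to the same %g-min grid slot (slot time %s): ambiguous sampling",
      interval,
      format(as.POSIXct(anchor + (k - 1L) * step, tz = "UTC",
                        origin = "1970-01-01"), tz = "UTC")
    ), call. = FALSE)
  }
  n <- max(slot)
  glucose <- rep(NA_real_, n)
  flag <- rep("missing", n)
  glucose[slot] <- series$samples$glucose
  flag[slot] <- series$samples$source_flag
  new_gridded_series(
    start = as.POSIXct(anchor, origin = "1970-01-01", tz = "UTC"),
    interval = interval, glucose = glucose, flag = flag
  )
}

#' Fill bounded gaps by linear interpolation
#'
#' Every maximal run of consecutive missing slots that is bounded by
#' observed slots on both sides and no longer than `max_gap` is filled
#' linearly between the bounding values and flagged `"interpolated"`.
#' Longer runs, and leading/trailing runs (which have only one bound),
#' are left missing: extrapolation would invent data. The operation is
#' idempotent, and every filled value lies within the closed interval
#' spanned by its two bounding observations.
#'
#' @param gridded a `gridded_series` with at least 2 observed slots.
#' @param max_gap largest run length (slot count) that may be filled;
#'   default 21 consecutive slots.
#' @return The gridded series with eligible gaps filled.
#' @examples
#' ts <- as.POSIXct("2024-01-01", tz = "UTC") + 300 * c(0, 2)
#' g <- align_to_grid(glucose_series(ts, c(100, 110)))
#' interpolate_gaps(g)$glucose  # 100 105 110
#' @export
interpolate_gaps <- function(gridded, max_gap = 21) {
  stopifnot(inherits(gridded, "gridded_series"))
  miss <- is.na(gridded$glucose)
  if (sum(!miss) < 2L) {
    stop("interpolation needs at least 2 observed slots", call. = FALSE)
  }
  if (!any(miss)) {
    return(gridded)
  }
  r <- rle(miss)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  n <- length(miss)
  for (j in seq_along(r$values)) {
    if (!r$values[j]) next
    a <- starts[j]
    b <- ends[j]
    if (a == 1L || b == n) next            # one-sided run: never extrapolated
    if (r$lengths[j] > max_gap) next       # run exceeds the cap
    lo <- gridded$glucose[a - 1L]
    hi <- gridded$glucose[b + 1L]
    len <- r$lengths[j]
    fill <- lo + (hi - lo) * seq_len(len) / (len + 1)
    gridded$glucose[a:b] <- fill
    gridded$flag[a:b] <- "interpolated"
  }
  gridded
}

#' Select an analysis window from a gridded series
#'
#' Restricts the series to a half-open window `[start, start + duration)`
#' on the same grid; a `duration`-minute window at a 5-minute interval
#' therefore holds `duration / 5` slots (48 h -> 576). Counts are implied
#' by the retained flags.
#'
#' @param gridded a `gridded_series`.
#' @param start window start (`POSIXct` or parseable string, UTC); must lie
#'   on the grid within the recording span.
#' @param duration window length in minutes.
#' @return The windowed `gridded_series`.
#' @export
select_window <- function(gridded, start, duration) {
  stopifnot(inherits(gridded, "gridded_series"))
  if (!inherits(start, "POSIXct")) {
    start <- as.POSIXct(start, tz = "UTC")
  }
  step <- 60 * gridded$interval
  off <- as.numeric(start) - as.numeric(gridded$start)
  if (abs(off / step - round(off / step)) > 1e-9) {
    stop("window start does not lie on the sampling grid", call. = FALSE)
  }
  first <- as.integer(round(off / step)) + 1L
  nslots <- as.integer(floor(duration / gridded$interval))
  last <- first + nslots - 1L
  n <- length(gridded$glucose)
  if (nslots < 1L) {
    stop("selected window is empty", call. = FALSE)
  }
  if (first < 1L || last > n) {
    stop("selected window lies outside the recording span", call. = FALSE)
  }
  new_gridded_series(
    start = gridded$start + (first - 1L) * step,
    interval = gridded$interval,
    glucose = gridded$glucose[first:last],
    flag = gridded$flag[first:last]
  )
}
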