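# Closed-form variability metrics on a gridded series.
#
# Conventions shared by all metrics:
#   * "observed" slots are measured or interpolated; interpolated slots
#     count as observed (gaps are filled before metrics are computed).
#   * Remaining missing slots are excluded slotwise (AUC, PATR/PBTR, SD)
#     or pairwise (CONGA, MODD): each metric's k counts only usable
#     observations.
#   * All thresholds and results are mg/dL.

observed_values <- function(gridded) {
  gridded$glucose[gridded$flag != "missing"]
}

#' Average exposure to hyperglycemia (Avg. AUC-H)
#'
#' Time-average of the positive exceedance `(G(t) - TR_H)+` over the
#' observed duration of the window:
#' `(1/T) * integral of (G(t) - TR_H) dt where G(t) > TR_H`.
#' Under the rectangle rule on a uniform grid this is the mean exceedance
#' over observed slots. A result of 10 mg/dL means that, averaged over the
#' whole observation, glucose exceeded the upper target bound by 10 mg/dL.
#' The comparison is strict: a slot exactly at `tr_high` contributes 0.
#'
#' @param gridded a `gridded_series` in mg/dL.
#' @param tr_high upper target-range bound, mg/dL.
#' @return Mean exceedance in mg/dL (>= 0), or `NA` if no slot is observed.
#' @examples
#' g <- new_gridded_series(as.POSIXct("2024-01-01", tz = "UTC"), 5,
#'                         rep(160, 12), rep("measured", 12))
#' avg_auc_high(g, 150)  # 10
#' @export
avg_auc_high <- function(gridded, tr_high) {
  v <- observed_values(gridded)
  if (length(v) == 0L) {
    return(NA_real_)
  }
  mean(pmax(v - tr_high, 0))
}

#' Average exposure to hypoglycemia (Avg. AUC-L)
#'
#' Mirror of [avg_auc_high()] with the negative exceedance:
#' `(1/T) * integral of (TR_L - G(t)) dt where G(t) < TR_L`.
#'
#' @param gridded a `gridded_series` in mg/dL.
#' @param tr_low lower target-range bound, mg/dL.
#' @return Mean exceedance below range in mg/dL (>= 0), or `NA` if no slot
#'   is observed.
#' @export
avg_auc_low <- function(gridded, tr_low) {
  v <- observed_values(gridded)
  if (length(v) == 0L) {
    return(NA_real_)
  }
  mean(pmax(tr_low - v, 0))
}

#' Percentage of time above/below/within the target range
#'
#' Slot-count percentages over observed slots (equivalent to time
#' percentages on a uniform grid): PATR uses `G > tr_high`, PBTR uses
#' `G < tr_low`; values exactly on a bound count as in range, consistent
#' with the strict inequalities of the AUC conditions.
#'
#' @param gridded a `gridded_series` in mg/dL.
#' @param range a [target_range()].
#' @return Named list `patr`, `pbtr`, `in_range` (percent; sums to 100),
#'   all `NA` if no slot is observed.
#' @export
time_in_ranges <- function(gridded, range) {
  stopifnot(inherits(range, "target_range"))
  v <- observed_values(gridded)
  if (length(v) == 0L) {
    return(list(patr = NA_real_, pbtr = NA_real_, in_range = NA_real_))
  }
  patr <- 100 * mean(v > range$tr_high)
  pbtr <- 100 * mean(v < range$tr_low)
  list(patr = patr, pbtr = pbtr, in_range = 100 - patr - pbtr)
}

# Differences at a fixed slot lag; both endpoints must be observed.
lag_differences <- function(gridded, lag_minutes) {
  lag_slots <- lag_minutes / gridded$interval
  if (abs(lag_slots - round(lag_slots)) > 1e-9) {
    stop(sprintf("lag of %g min is not a whole number of %g-min slots",
                 lag_minutes, gridded$interval), call. = FALSE)
  }
  lag_slots <- as.integer(round(lag_slots))
  v <- gridded$glucose
  v[gridded$flag == "missing"] <- NA
  n <- length(v)
  if (lag_slots >= n) {
    return(numeric(0))
  }
  d <- v[(lag_slots + 1L):n] - v[1L:(n - lag_slots)]
  d[!is.na(d)]
}

#' Continuous overall net glycemic action, CONGA(n)
#'
#' Sample standard deviation of the glucose differences at a lag of
#' `n` hours: with `D_t = BG_t - BG_(t - n*60min)` over the `k` slots where
#' both endpoints are observed, returns
#' `sqrt( sum((D_t - mean(D))^2) / (k - 1) )`.
#' Captures short-term, within-day variability; the conventional order is
#' `n = 1` (a 12-slot lag on the 5-minute grid).
#'
#' @param gridded a `gridded_series` in mg/dL.
#' @param n lag in hours (default 1).
#' @return CONGA(n) in mg/dL, or `NA` when fewer than 2 usable pairs exist.
#' @export
conga <- function(gridded, n = 1) {
  d <- lag_differences(gridded, n * 60)
  if (length(d) < 2L) {
    return(NA_real_)
  }
  stats::sd(d)
}

#' Mean of daily differences (MODD)
#'
#' Mean absolute difference between glucose values exactly 24 h
#' (1,440 min) apart: `sum(|BG_t - BG_(t-1440)|) / k` over the `k` slot
#' pairs where both readings are observed. Captures between-day
#' variability; requires a recording spanning more than 24 h.
#'
#' @param gridded a `gridded_series` in mg/dL.
#' @return MODD in mg/dL, or `NA` when the span is <= 24 h or no pair is
#'   usable.
#' @export
modd <- function(gridded) {
  span_min <- (length(gridded$glucose) - 1L) * gridded$interval
  if (span_min < 1440) {
    return(NA_real_)
  }
  d <- lag_differences(gridded, 1440)
  if (length(d) == 0L) {
    return(NA_real_)
  }
  mean(abs(d))
}

#' Standard deviation of the glucose values
#'
#' Sample standard deviation (denominator `N - 1`) over all observed
#' (measured + interpolated) slots.
#'
#' @param gridded a `gridded_series` in mg/dL.
#' @return SD in mg/dL, or `NA` with fewer than 2 observed slots.
#' @export
glucose_sd <- function(gridded) {
  v <- observed_values(gridded)
  if (length(v) < 2L) {
    return(NA_real_)
  }
  stats::sd(v)
}
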