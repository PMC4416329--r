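# Modified Baghurst MAGE.
#
# Pipeline per fully-observed segment:
#   1. relocate the start point when no meaningful excursion (ME) is
#      reachable from the first sample although the curve contains MEs;
#   2. detect turning points (strict local extrema + endpoints, plateaus
#      collapsed to their first slot);
#   3. prune sub-ME turning points to a fixed point, retaining W/M
#      patterns (a center strictly less extreme than both like-kind
#      neighbors survives even when sub-ME on both sides);
#   4. recheck the stretch before the first detected ME for missed MEs;
#   5. average the amplitudes of the countable (> ME) excursions.
#
# Turning points are data frames with columns slot, glucose, kind
# ("peak"/"nadir"); excursions with from_slot, from_glucose, to_slot,
# to_glucose, amplitude, direction ("up"/"down").

empty_turning_points <- function() {
  data.frame(slot = integer(0), glucose = numeric(0),
             kind = character(0), stringsAsFactors = FALSE)
}

# Core detector on a plain numeric vector (no NAs); slots are 1-based
# positions in v.
tp_detect <- function(v) {
  n <- length(v)
  if (n < 3L) {
    return(empty_turning_points())
  }
  # collapse plateaus: keep the first slot of each run of equal values
  idx <- c(1L, which(diff(v) != 0) + 1L)
  w <- v[idx]
  m <- length(w)
  if (m < 2L) {
    return(empty_turning_points())   # constant series: no excursions
  }
  d <- sign(diff(w))
  keep <- logical(m)
  kind <- character(m)
  keep[1L] <- TRUE
  kind[1L] <- if (d[1L] > 0) "nadir" else "peak"
  keep[m] <- TRUE
  kind[m] <- if (d[m - 1L] > 0) "peak" else "nadir"
  if (m > 2L) {
    for (i in 2L:(m - 1L)) {
      if (d[i - 1L] != d[i]) {
        keep[i] <- TRUE
        kind[i] <- if (d[i - 1L] > 0) "peak" else "nadir"
      }
    }
  }
  data.frame(slot = idx[keep], glucose = w[keep], kind = kind[keep],
             stringsAsFactors = FALSE)
}

#' Detect turning points of a glucose curve
#'
#' Returns every strict local maximum/minimum plus the two endpoints of
#' the curve, alternating peak/nadir. Plateaus (runs of equal values) are
#' collapsed to a single point at the plateau's first slot. This is the
#' raw input to the MAGE pruning stage.
#'
#' @param gridded a fully observed `gridded_series` (interpolate or window
#'   first; residual missing slots are an error here — [compute_mage()]
#'   handles them by segmenting), or a plain numeric vector.
#' @return Data frame with columns `slot` (1-based grid position),
#'   `glucose` (mg/dL) and `kind` (`"peak"`/`"nadir"`). Fewer than 3 slots
#'   (or a constant series) yield zero rows.
#' @export
find_turning_points <- function(gridded) {
  if (is.numeric(gridded)) {
    v <- gridded
  } else {
    stopifnot(inherits(gridded, "gridded_series"))
    v <- gridded$glucose
  }
  if (anyNA(v)) {
    stop("series has missing slots; interpolate or segment before turning-point detection",
         call. = FALSE)
  }
  tp_detect(v)
}

# W/M centers: points strictly less extreme than BOTH like-kind neighbors
# (peak lower than the adjacent peaks, nadir higher than the adjacent
# nadirs). Returns a logical vector along pts.
wm_centers <- function(pts) {
  n <- nrow(pts)
  out <- logical(n)
  if (n < 5L) {
    return(out)
  }
  for (i in 3L:(n - 2L)) {
    g <- pts$glucose
    if (pts$kind[i] == "peak") {
      out[i] <- g[i] < g[i - 2L] && g[i] < g[i + 2L]
    } else {
      out[i] <- g[i] > g[i - 2L] && g[i] > g[i + 2L]
    }
  }
  out
}

# Delete interior point i and merge its now-adjacent like-kind neighbors,
# keeping the more extreme one (tie -> the earlier).
delete_and_merge <- function(pts, i) {
  a <- i - 1L
  b <- i + 1L
  g <- pts$glucose
  if (pts$kind[a] == "peak") {
    drop <- if (g[a] >= g[b]) b else a
  } else {
    drop <- if (g[a] <= g[b]) b else a
  }
  pts[-c(i, drop), , drop = FALSE]
}

#' Prune sub-threshold turning points (modified Baghurst)
#'
#' Iteratively removes turning points associated with uncountable
#' (amplitude <= `me`) excursions until a fixed point:
#' \itemize{
#'   \item a point sub-ME on both sides is deleted (its two like-kind
#'     neighbors merge, keeping the more extreme; ties keep the earlier)
#'     \emph{unless} it is the center of a W/M pattern — strictly less
#'     extreme than both like-kind neighbors — which is retained
#'     throughout, the departure from the original Baghurst procedure;
#'   \item a sub-ME excursion whose two bounding points each have a
#'     countable excursion on their other side is removed by deleting both
#'     bounding points (the sub-ME wiggle inside a large swing);
#'   \item an endpoint whose single excursion is sub-ME is dropped, unless
#'     it is the like-kind neighbor propping up a W/M center.
#' }
#' Because W/M centers survive, the final curve may still contain
#' excursions at or below `me`; [compute_mage()] raises the visual-analysis
#' alert in that case.
#'
#' @param points alternating turning-point data frame from
#'   [find_turning_points()].
#' @param me meaningful-excursion threshold, mg/dL.
#' @return The retained turning points (same columns, kinds alternating).
#' @export
prune_turning_points <- function(points, me) {
  pts <- points
  repeat {
    n <- nrow(pts)
    if (n < 2L) {
      break
    }
    amps <- abs(diff(pts$glucose))
    wm <- wm_centers(pts)
    changed <- FALSE

    # pass A: interior points sub-ME on both sides
    if (n >= 3L) {
      for (i in 2L:(n - 1L)) {
        if (amps[i - 1L] <= me && amps[i] <= me && !wm[i]) {
          pts <- delete_and_merge(pts, i)
          changed <- TRUE
          break
        }
      }
    }
    if (changed) next

    # pass C: sub-ME excursion inside countable swings on both outer sides
    if (n >= 4L) {
      for (i in 2L:(n - 2L)) {
        if (amps[i] <= me && amps[i - 1L] > me && amps[i + 1L] > me &&
            !wm[i] && !wm[i + 1L]) {
          pts <- pts[-c(i, i + 1L), , drop = FALSE]
          changed <- TRUE
          break
        }
      }
    }
    if (changed) next

    # pass B: endpoints with a single sub-ME excursion
    if (amps[1L] <= me && !(n >= 3L && wm[3L])) {
      pts <- pts[-1L, , drop = FALSE]
      changed <- TRUE
    } else if (amps[n - 1L] <= me && !(n >= 3L && wm[n - 2L])) {
      pts <- pts[-n, , drop = FALSE]
      changed <- TRUE
    }
    if (!changed) break
  }
  rownames(pts) <- NULL
  pts
}

excursions_from_points <- function(pts) {
  n <- nrow(pts)
  if (n < 2L) {
    return(data.frame(from_slot = integer(0), from_glucose = numeric(0),
                      to_slot = integer(0), to_glucose = numeric(0),
                      amplitude = numeric(0), direction = character(0),
                      stringsAsFactors = FALSE))
  }
  from <- pts[-n, ]
  to <- pts[-1L, ]
  data.frame(
    from_slot = from$slot, from_glucose = from$glucose,
    to_slot = to$slot, to_glucose = to$glucose,
    amplitude = abs(to$glucose - from$glucose),
    direction = ifelse(to$glucose > from$glucose, "up", "down"),
    stringsAsFactors = FALSE
  )
}

# Does the curve contain a meaningful excursion anywhere (some monotone
# run with amplitude > me)?
contains_me <- function(v, me) {
  pts <- tp_detect(v)
  nrow(pts) >= 2L && any(abs(diff(pts$glucose)) > me)
}

#' Choose the MAGE start point
#'
#' Taking the first sample `G(t1)` as reference: when neither
#' `G(t)MAX - G(t1) > me` nor `G(t1) - G(t)MIN > me` although the curve
#' does contain meaningful excursions, no ME is reachable from the first
#' sample and the start point is moved to the global extremum (`G(t)MAX`
#' or `G(t)MIN`, whichever occurs first). Otherwise the start stays at the
#' first slot.
#'
#' @param gridded a fully observed `gridded_series` or numeric vector.
#' @param me meaningful-excursion threshold, mg/dL (default 45).
#' @return 1-based slot index of the start point.
#' @export
select_start_point <- function(gridded, me = 45) {
  v <- if (is.numeric(gridded)) gridded else {
    stopifnot(inherits(gridded, "gridded_series"))
    gridded$glucose
  }
  if (anyNA(v)) {
    stop("series has missing slots; interpolate or segment first",
         call. = FALSE)
  }
  if (length(v) < 3L) {
    return(1L)
  }
  g1 <- v[1L]
  if (max(v) - g1 > me || g1 - min(v) > me) {
    return(1L)
  }
  if (!contains_me(v, me)) {
    return(1L)
  }
  min(which.max(v), which.min(v))
}

#' Recheck the curve before the first detected excursion
#'
#' After the first meaningful excursion (ME) is identified, the slots
#' between the (possibly relocated) start point's segment origin and the
#' first ME's origin are re-scanned with the same turning-point detection
#' and pruning; any ME found there was missed by the main pass (it can
#' only live in the stretch skipped by a relocated start point) and is
#' returned for prepending to the excursion list in temporal order.
#'
#' @param gridded a fully observed `gridded_series` or numeric vector
#'   (the whole analysis segment, from its first slot).
#' @param first_me single-row excursion data frame (the first ME found by
#'   the main pass; its `from_slot` bounds the re-scan).
#' @param me meaningful-excursion threshold, mg/dL.
#' @return Excursion data frame of missed MEs (possibly zero rows),
#'   temporal order, duplicates of the main pass excluded by slot pair.
#' @export
backtrack_recheck <- function(gridded, first_me, me = 45) {
  v <- if (is.numeric(gridded)) gridded else {
    stopifnot(inherits(gridded, "gridded_series"))
    gridded$glucose
  }
  stop_at <- first_me$from_slot[1L]
  if (stop_at < 3L) {
    return(excursions_from_points(empty_turning_points()))
  }
  region <- v[1L:stop_at]
  pts <- prune_turning_points(tp_detect(region), me)
  exc <- excursions_from_points(pts)
  exc <- exc[exc$amplitude > me, , drop = FALSE]
  # never duplicate the first ME itself
  dup <- exc$from_slot == first_me$from_slot[1L] &
    exc$to_slot == first_me$to_slot[1L]
  exc <- exc[!dup & exc$to_slot <= stop_at, , drop = FALSE]
  rownames(exc) <- NULL
  exc
}

# Run the full MAGE pipeline on one fully observed segment. Slots in the
# result are absolute grid positions (offset added).
mage_segment <- function(v, me, offset = 0L) {
  start <- select_start_point(v, me)
  pts <- tp_detect(v[start:length(v)])
  if (nrow(pts) > 0L) {
    pts$slot <- pts$slot + start - 1L
  }
  pruned <- prune_turning_points(pts, me)
  exc <- excursions_from_points(pruned)
  alert <- nrow(exc) > 0L && any(exc$amplitude <= me)

  counted <- exc[exc$amplitude > me, , drop = FALSE]
  if (nrow(counted) > 0L) {
    first_me <- counted[1L, , drop = FALSE]
    missed <- backtrack_recheck(v, first_me, me)
    if (nrow(missed) > 0L) {
      counted <- rbind(missed, counted)
      # retain the re-scanned points alongside the main ones
      extra <- data.frame(
        slot = c(missed$from_slot, missed$to_slot),
        glucose = c(missed$from_glucose, missed$to_glucose),
        kind = c(ifelse(missed$direction == "up", "nadir", "peak"),
                 ifelse(missed$direction == "up", "peak", "nadir")),
        stringsAsFactors = FALSE
      )
      pruned <- rbind(extra[!extra$slot %in% pruned$slot, , drop = FALSE],
                      pruned)
      pruned <- pruned[order(pruned$slot), , drop = FALSE]
    }
  }

  if (offset != 0L) {
    adj <- function(df, cols) {
      for (cl in cols) df[[cl]] <- df[[cl]] + offset
      df
    }
    pruned <- adj(pruned, "slot")
    counted <- adj(counted, c("from_slot", "to_slot"))
    exc <- adj(exc, c("from_slot", "to_slot"))
  }
  rownames(pruned) <- rownames(counted) <- rownames(exc) <- NULL
  list(points = pruned, excursions = exc, counted = counted, alert = alert)
}

#' Mean amplitude of glycemic excursions (MAGE)
#'
#' Computes MAGE with a modified Baghurst turning-point procedure: start
#' point relocation ([select_start_point()]), turning-point detection
#' ([find_turning_points()]), sub-threshold pruning with W/M-pattern
#' retention ([prune_turning_points()]) and a recheck of the stretch
#' before the first detected excursion ([backtrack_recheck()]).
#'
#' `MAGE+` / `MAGE-` are the means of the upward / downward excursion
#' amplitudes exceeding the meaningful-excursion threshold
#' (`sum(lambda)/n for lambda > me`); `MAGE avg.` averages the defined
#' MAGEs (it equals the one-sided value when only one direction has
#' countable excursions). The excursion frequency counts countable
#' excursions in both directions. When the retained curve still contains
#' a sub-ME excursion (possible only through W/M retention), the
#' visual-analysis alert is set.
#'
#' Residual missing runs (gaps longer than the interpolation cap) split
#' the window into independent segments; MAGE is computed per segment and
#' pooled over the combined amplitude list.
#'
#' @param gridded a `gridded_series` in mg/dL (interpolate gaps first), or
#'   a plain numeric vector.
#' @param me meaningful-excursion threshold nu, mg/dL; default 45. The
#'   classical 1-SD threshold is deliberately not used: excursions are
#'   counted against this fixed, user-adjustable bound.
#' @return An object of class `mage_result`: list with `mage_plus`,
#'   `mage_minus`, `mage_avg` (mg/dL, `NA` when undefined),
#'   `excursion_frequency`, `me`, `alert_visual_analysis`,
#'   `retained_points` (turning-point data frame) and `excursions`
#'   (countable excursions, temporal order).
#' @examples
#' saw <- rep(c(100, 160), length.out = 7)  # 6 swings of 60 mg/dL
#' compute_mage(saw, me = 45)
#' @export
compute_mage <- function(gridded, me = 45) {
  v <- if (is.numeric(gridded)) gridded else {
    stopifnot(inherits(gridded, "gridded_series"))
    out <- gridded$glucose
    out[gridded$flag == "missing"] <- NA
    out
  }

  points <- empty_turning_points()
  counted <- excursions_from_points(empty_turning_points())
  alert <- FALSE

  if (length(v) > 0L) {
    ok <- !is.na(v)
    r <- rle(ok)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in seq_along(r$values)) {
      if (!r$values[j] || r$lengths[j] < 3L) next
      seg <- mage_segment(v[starts[j]:ends[j]], me, offset = starts[j] - 1L)
      points <- rbind(points, seg$points)
      counted <- rbind(counted, seg$counted)
      alert <- alert || seg$alert
    }
  }

  up <- counted$amplitude[counted$direction == "up"]
  down <- counted$amplitude[counted$direction == "down"]
  mage_plus <- if (length(up) > 0L) mean(up) else NA_real_
  mage_minus <- if (length(down) > 0L) mean(down) else NA_real_
  defined <- c(mage_plus, mage_minus)
  defined <- defined[!is.na(defined)]
  mage_avg <- if (length(defined) > 0L) mean(defined) else NA_real_

  structure(
    list(
      mage_plus = mage_plus,
      mage_minus = mage_minus,
      mage_avg = mage_avg,
      excursion_frequency = nrow(counted),
      me = me,
      alert_visual_analysis = alert,
      retained_points = points,
      excursions = counted
    ),
    class = "mage_result"
  )
}

#' @export
print.mage_result <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "undefined" else sprintf("%.2f mg/dL", v)
  cat("<mage_result>\n")
  cat("  MAGE+ :", fmt(x$mage_plus), "\n")
  cat("  MAGE- :", fmt(x$mage_minus), "\n")
  cat("  MAGE avg.:", fmt(x$mage_avg), "\n")
  cat("  excursion frequency:", x$excursion_frequency,
      sprintf("(ME = %g mg/dL)\n", x$me))
  if (isTRUE(x$alert_visual_analysis)) {
    cat("  Visual analysis should be performed, see User Documentation\n")
  }
  invisible(x)
}
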