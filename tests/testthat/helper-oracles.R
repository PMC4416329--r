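# Independent brute-force oracles. Everything here is written with plain
# loops straight from the metric definitions and shares no code with the
# package internals.

# mg/dL vector with NA for missing slots
gridded_vec <- function(g) {
  v <- g$glucose
  v[g$flag == "missing"] <- NA
  v
}

oracle_sd <- function(v) {
  v <- v[!is.na(v)]
  n <- length(v)
  if (n < 2) return(NA_real_)
  m <- 0
  for (x in v) m <- m + x
  m <- m / n
  s <- 0
  for (x in v) s <- s + (x - m)^2
  sqrt(s / (n - 1))
}

oracle_conga <- function(v, interval, n_hours = 1) {
  lag <- as.integer(n_hours * 60 / interval)
  d <- c()
  for (t in seq_along(v)) {
    if (t > lag && !is.na(v[t]) && !is.na(v[t - lag])) {
      d <- c(d, v[t] - v[t - lag])
    }
  }
  k <- length(d)
  if (k < 2) return(NA_real_)
  dbar <- sum(d) / k
  s <- 0
  for (x in d) s <- s + (x - dbar)^2
  sqrt(s / (k - 1))
}

oracle_modd <- function(v, interval) {
  if ((length(v) - 1) * interval < 1440) return(NA_real_)
  lag <- as.integer(1440 / interval)
  tot <- 0
  k <- 0
  for (t in seq_along(v)) {
    if (t > lag && !is.na(v[t]) && !is.na(v[t - lag])) {
      tot <- tot + abs(v[t] - v[t - lag])
      k <- k + 1
    }
  }
  if (k == 0) return(NA_real_)
  tot / k
}

oracle_auc_high <- function(v, trh) {
  v <- v[!is.na(v)]
  if (length(v) == 0) return(NA_real_)
  tot <- 0
  for (x in v) if (x > trh) tot <- tot + (x - trh)
  tot / length(v)
}

oracle_auc_low <- function(v, trl) {
  v <- v[!is.na(v)]
  if (length(v) == 0) return(NA_real_)
  tot <- 0
  for (x in v) if (x < trl) tot <- tot + (trl - x)
  tot / length(v)
}

oracle_patr <- function(v, trh) {
  v <- v[!is.na(v)]
  n_above <- 0
  for (x in v) if (x > trh) n_above <- n_above + 1
  100 * n_above / length(v)
}

oracle_pbtr <- function(v, trl) {
  v <- v[!is.na(v)]
  n_below <- 0
  for (x in v) if (x < trl) n_below <- n_below + 1
  100 * n_below / length(v)
}

# ---- naive MAGE re-implementation ------------------------------------
#
# Works on an index mask over the original vector; after every deletion
# the turning points are re-derived from scratch from the surviving
# subsequence (which realizes the like-kind merge "keep the more extreme,
# tie earlier" automatically: the weaker duplicate stops being a local
# extremum of the restricted sequence).

oracle_turning <- function(v, slots = seq_along(v)) {
  # collapse plateaus, keep first slot of each run
  keep <- c()
  last <- NA
  for (i in seq_along(v)) {
    if (is.na(last) || v[i] != last) keep <- c(keep, i)
    last <- v[i]
  }
  w <- v[keep]
  if (length(w) < 2) {
    return(data.frame(slot = integer(0), glucose = numeric(0),
                      kind = character(0)))
  }
  rows <- list()
  m <- length(w)
  for (i in seq_len(m)) {
    if (i == 1) {
      kind <- if (w[2] > w[1]) "nadir" else "peak"
    } else if (i == m) {
      kind <- if (w[m] > w[m - 1]) "peak" else "nadir"
    } else if (w[i] > w[i - 1] && w[i] > w[i + 1]) {
      kind <- "peak"
    } else if (w[i] < w[i - 1] && w[i] < w[i + 1]) {
      kind <- "nadir"
    } else {
      next
    }
    rows[[length(rows) + 1]] <- data.frame(
      slot = slots[keep[i]], glucose = w[i], kind = kind)
  }
  do.call(rbind, rows)
}

oracle_is_wm <- function(pts, i) {
  n <- nrow(pts)
  if (i < 3 || i > n - 2) return(FALSE)
  if (pts$kind[i] == "peak") {
    pts$glucose[i] < pts$glucose[i - 2] && pts$glucose[i] < pts$glucose[i + 2]
  } else {
    pts$glucose[i] > pts$glucose[i - 2] && pts$glucose[i] > pts$glucose[i + 2]
  }
}

# retain_wm = FALSE gives the original (unmodified) pruning in which W/M
# centers are deleted like any other sub-threshold point.
oracle_prune <- function(v, slots, me, retain_wm = TRUE) {
  is_wm <- function(pts, i) retain_wm && oracle_is_wm(pts, i)
  active <- oracle_turning(v, slots)$slot
  repeat {
    idx <- match(active, slots)
    pts <- oracle_turning(v[idx], slots = active)
    active <- pts$slot
    n <- nrow(pts)
    if (n < 2) break
    amp <- abs(pts$glucose[-1] - pts$glucose[-n])
    removed <- NULL
    # interior point sub-ME on both sides (non-W/M); the deletion merges
    # the two like-kind neighbors, keeping the more extreme (tie: earlier)
    for (i in 2:(n - 1)) {
      if (n >= 3 && amp[i - 1] <= me && amp[i] <= me && !is_wm(pts, i)) {
        ga <- pts$glucose[i - 1]
        gb <- pts$glucose[i + 1]
        if (pts$kind[i - 1] == "peak") {
          weaker <- if (ga >= gb) pts$slot[i + 1] else pts$slot[i - 1]
        } else {
          weaker <- if (ga <= gb) pts$slot[i + 1] else pts$slot[i - 1]
        }
        removed <- c(pts$slot[i], weaker)
        break
      }
    }
    # sub-ME wiggle inside countable swings
    if (is.null(removed) && n >= 4) {
      for (i in 2:(n - 2)) {
        if (amp[i] <= me && amp[i - 1] > me && amp[i + 1] > me &&
            !is_wm(pts, i) && !is_wm(pts, i + 1)) {
          removed <- pts$slot[c(i, i + 1)]
          break
        }
      }
    }
    # endpoints
    if (is.null(removed)) {
      if (amp[1] <= me && !is_wm(pts, 3)) {
        removed <- pts$slot[1]
      } else if (amp[n - 1] <= me && !is_wm(pts, n - 2)) {
        removed <- pts$slot[n]
      }
    }
    if (is.null(removed)) break
    active <- setdiff(active, removed)
  }
  idx <- match(active, slots)
  oracle_turning(v[idx], slots = active)
}

oracle_excursions <- function(pts) {
  n <- if (is.null(pts)) 0 else nrow(pts)
  if (n < 2) {
    return(data.frame(from_slot = integer(0), to_slot = integer(0),
                      amplitude = numeric(0), direction = character(0)))
  }
  rows <- list()
  for (i in 1:(n - 1)) {
    rows[[i]] <- data.frame(
      from_slot = pts$slot[i], to_slot = pts$slot[i + 1],
      amplitude = abs(pts$glucose[i + 1] - pts$glucose[i]),
      direction = if (pts$glucose[i + 1] > pts$glucose[i]) "up" else "down")
  }
  do.call(rbind, rows)
}

oracle_start <- function(v, me) {
  gmax <- v[1]; imax <- 1
  gmin <- v[1]; imin <- 1
  for (i in seq_along(v)) {
    if (v[i] > gmax) { gmax <- v[i]; imax <- i }
    if (v[i] < gmin) { gmin <- v[i]; imin <- i }
  }
  if (gmax - v[1] > me || v[1] - gmin > me) return(1)
  tp <- oracle_turning(v)
  has_me <- FALSE
  if (!is.null(tp) && nrow(tp) >= 2) {
    for (i in 1:(nrow(tp) - 1)) {
      if (abs(tp$glucose[i + 1] - tp$glucose[i]) > me) has_me <- TRUE
    }
  }
  if (!has_me) return(1)
  min(imax, imin)
}

# Full modified-Baghurst pipeline on one fully observed segment.
oracle_mage_segment <- function(v, me) {
  n <- length(v)
  start <- oracle_start(v, me)
  pts <- oracle_prune(v[start:n], slots = start:n, me = me)
  exc <- oracle_excursions(pts)
  alert <- nrow(exc) > 0 && any(exc$amplitude <= me)
  counted <- exc[exc$amplitude > me, , drop = FALSE]
  if (nrow(counted) > 0 && counted$from_slot[1] >= 3) {
    stop_at <- counted$from_slot[1]
    bpts <- oracle_prune(v[1:stop_at], slots = 1:stop_at, me = me)
    bexc <- oracle_excursions(bpts)
    bexc <- bexc[bexc$amplitude > me, , drop = FALSE]
    dup <- bexc$from_slot == counted$from_slot[1] &
      bexc$to_slot == counted$to_slot[1]
    bexc <- bexc[!dup, , drop = FALSE]
    counted <- rbind(bexc, counted)
  }
  list(counted = counted, alert = alert)
}

oracle_mage <- function(v, me = 45) {
  segs <- list()
  cur <- c()
  for (i in seq_along(v)) {
    if (is.na(v[i])) {
      if (length(cur) >= 3) segs[[length(segs) + 1]] <- cur
      cur <- c()
    } else {
      cur <- c(cur, v[i])
    }
  }
  if (length(cur) >= 3) segs[[length(segs) + 1]] <- cur
  amps_up <- c(); amps_down <- c(); alert <- FALSE; ef <- 0
  for (s in segs) {
    res <- oracle_mage_segment(s, me)
    alert <- alert || res$alert
    ef <- ef + nrow(res$counted)
    amps_up <- c(amps_up, res$counted$amplitude[res$counted$direction == "up"])
    amps_down <- c(amps_down,
                   res$counted$amplitude[res$counted$direction == "down"])
  }
  mp <- if (length(amps_up)) mean(amps_up) else NA_real_
  mm <- if (length(amps_down)) mean(amps_down) else NA_real_
  d <- c(mp, mm); d <- d[!is.na(d)]
  list(mage_plus = mp, mage_minus = mm,
       mage_avg = if (length(d)) mean(d) else NA_real_,
       excursion_frequency = ef, alert = alert)
}

# Definition-level check on the excursion count: dynamic program for the
# maximum number of alternating excursions, each exceeding `me`, over all
# subsequences of the series. Independent of any turning-point logic.
oracle_max_excursions <- function(v, me) {
  n <- length(v)
  if (n < 2) return(0)
  up <- rep(0, n)    # best count of a chain ending at i with an up-move
  down <- rep(0, n)  # ... with a down-move
  best <- 0
  for (j in 2:n) {
    for (i in 1:(j - 1)) {
      if (v[j] - v[i] > me) {
        cand <- max(down[i], 0) + 1
        if (cand > up[j]) up[j] <- cand
      }
      if (v[i] - v[j] > me) {
        cand <- max(up[i], 0) + 1
        if (cand > down[j]) down[j] <- cand
      }
    }
    best <- max(best, up[j], down[j])
  }
  best
}
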