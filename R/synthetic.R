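# Seeded synthetic CGM fixtures with known variability structure.
#
# The generator emulates the study conditions the metrics are meant for:
# a 5-minute-grid glucose series one to two days long, around a
# normoglycemic baseline, with optional sensor-like Gaussian noise and
# injected missing runs. A 48 h window on the half-open convention
# [start, start + T) holds T*60/interval slots (48 h -> 576; a full day
# -> 288 points, the daily maximum of a 5-min CGM).

FIXTURE_KINDS <- c("constant", "ramp", "sinusoid", "sawtooth",
                   "square_wave", "random_walk")

#' Specify a synthetic CGM fixture
#'
#' @param kind waveform: `"constant"`, `"ramp"` (linear rise of
#'   `amplitude` over the whole span), `"sinusoid"`
#'   (`baseline + amplitude * sin(2*pi*t/period)`), `"sawtooth"` (triangle
#'   zigzag between `baseline - amplitude` and `baseline + amplitude`,
#'   full cycle = `period`), `"square_wave"` (first half of each period at
#'   `baseline + amplitude`, second half at `baseline - amplitude`) or
#'   `"random_walk"` (Gaussian steps of SD `amplitude` per slot, reflected
#'   at 40 and 400 mg/dL to stay physiologic).
#' @param duration_hours recording length, hours (default 48, the usual
#'   analysis window).
#' @param interval slot spacing, minutes (default 5).
#' @param baseline center level, mg/dL (default 100, normoglycemia).
#' @param amplitude waveform amplitude (or step SD), mg/dL.
#' @param period waveform period, minutes.
#' @param noise_sd SD of additive Gaussian sensor noise, mg/dL (default 0).
#' @param gap_runs list of `c(start_slot, length)` pairs: runs of samples
#'   deleted from the output (1-based slots), surfacing as grid gaps.
#' @param seed integer seed making the fixture deterministic.
#' @param start timestamp of the first slot (UTC).
#' @return An object of class `fixture_spec`.
#' @export
fixture_spec <- function(kind, duration_hours = 48, interval = 5,
                         baseline = 100, amplitude = 0, period = 240,
                         noise_sd = 0, gap_runs = list(), seed = 1L,
                         start = as.POSIXct("2024-01-01 00:00:00",
                                            tz = "UTC")) {
  kind <- match.arg(kind, FIXTURE_KINDS)
  stopifnot(duration_hours > 0, interval > 0, amplitude >= 0,
            noise_sd >= 0, period > 0)
  n <- as.integer(round(duration_hours * 60 / interval))
  for (run in gap_runs) {
    if (length(run) != 2L || run[1L] < 1L || run[1L] + run[2L] - 1L > n) {
      stop("gap run outside the recording span", call. = FALSE)
    }
  }
  structure(
    list(kind = kind, duration_hours = duration_hours, interval = interval,
         baseline = baseline, amplitude = amplitude, period = period,
         noise_sd = noise_sd, gap_runs = gap_runs, seed = as.integer(seed),
         start = start, n_slots = n),
    class = "fixture_spec"
  )
}

# Triangle wave on [-1, 1], full cycle length 1, starting at -1 (nadir),
# peaking at phase 0.5.
triangle_wave <- function(phase) {
  p <- phase - floor(phase)
  ifelse(p < 0.5, -1 + 4 * p, 3 - 4 * p)
}

#' Generate a synthetic glucose series
#'
#' Samples the waveform of a [fixture_spec()] on its grid, adds seeded
#' Gaussian noise, deletes the listed gap runs, and returns the result as
#' a [glucose_series()] (mg/dL). Deterministic given the spec's seed.
#'
#' @param spec a [fixture_spec()].
#' @return A [glucose_series()] whose timestamps sit exactly on the grid,
#'   with the gap-run samples absent.
#' @export
generate_series <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  n <- spec$n_slots
  t_min <- spec$interval * (seq_len(n) - 1)   # minutes since start
  base <- switch(spec$kind,
    constant = rep(spec$baseline, n),
    ramp = spec$baseline + spec$amplitude * t_min / max(t_min[n], 1),
    sinusoid = spec$baseline +
      spec$amplitude * sin(2 * pi * t_min / spec$period),
    sawtooth = spec$baseline +
      spec$amplitude * triangle_wave(t_min / spec$period),
    square_wave = spec$baseline + spec$amplitude *
      ifelse((t_min %% spec$period) < spec$period / 2, 1, -1),
    random_walk = {
      withr_seed <- spec$seed
      old <- .Random.seed_save()
      on.exit(.Random.seed_restore(old), add = TRUE)
      set.seed(withr_seed)
      steps <- stats::rnorm(n - 1L, mean = 0, sd = spec$amplitude)
      reflect_walk(spec$baseline, steps, lower = 40, upper = 400)
    }
  )
  if (spec$noise_sd > 0) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(spec$seed + 1L)
    base <- base + stats::rnorm(n, sd = spec$noise_sd)
  }
  base <- pmax(base, 1)   # glucose must stay positive

  keep <- rep(TRUE, n)
  for (run in spec$gap_runs) {
    keep[run[1L]:(run[1L] + run[2L] - 1L)] <- FALSE
  }
  glucose_series(
    timestamp = spec$start + 60 * t_min[keep],
    glucose = base[keep],
    unit = "mg_dL",
    nominal_interval = spec$interval
  )
}

# Save/restore the global RNG state so fixture generation does not
# disturb a caller's random stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

# Random walk with reflecting barriers keeping values physiologic.
reflect_walk <- function(start, steps, lower, upper) {
  out <- numeric(length(steps) + 1L)
  out[1L] <- start
  x <- start
  for (i in seq_along(steps)) {
    x <- x + steps[i]
    if (x < lower) x <- 2 * lower - x
    if (x > upper) x <- 2 * upper - x
    out[i + 1L] <- x
  }
  out
}

#' Closed-form expected metric for an analytic fixture
#'
#' For noise-free fixtures whose waveform admits a closed form, returns
#' the exact value the pipeline must reproduce; returns `NULL` when no
#' closed form exists for the requested metric/fixture combination. This
#' registry is the test oracle that makes every metric checkable without
#' real recordings.
#'
#' Covered: `conga` (0 for constant and ramp, and for any waveform whose
#' period divides the lag), `modd` (0 for constant and for 24 h-periodic
#' waveforms), `sd` (0 for constant), `avg_auc_high` / `avg_auc_low`
#' (constant and square-wave rectangle areas), `patr` / `pbtr` (constant
#' and square wave), `mage_avg` / `mage_plus` / `mage_minus` (constant:
#' undefined; sawtooth: the 2*amplitude swing when it exceeds `me`, else
#' undefined).
#'
#' @param spec a [fixture_spec()] with `noise_sd = 0`.
#' @param metric one of `"conga"`, `"modd"`, `"sd"`, `"avg_auc_high"`,
#'   `"avg_auc_low"`, `"patr"`, `"pbtr"`, `"mage_plus"`, `"mage_minus"`,
#'   `"mage_avg"`.
#' @param params named list of metric parameters (`n` for CONGA lag in
#'   hours, `tr_high`/`tr_low` in mg/dL, `me` in mg/dL).
#' @return The expected value (`NA` meaning "undefined"), or `NULL` when
#'   no closed form is registered.
#' @export
known_answer <- function(spec, metric, params = list()) {
  stopifnot(inherits(spec, "fixture_spec"))
  if (spec$noise_sd != 0) {
    return(NULL)
  }
  k <- spec$kind
  A <- spec$amplitude
  periodic <- k %in% c("sinusoid", "sawtooth", "square_wave")
  divides <- function(lag_min) {
    periodic && abs(lag_min / spec$period -
                      round(lag_min / spec$period)) < 1e-9
  }
  switch(metric,
    conga = {
      n <- if (is.null(params$n)) 1 else params$n
      if (k %in% c("constant", "ramp")) 0
      else if (divides(n * 60)) 0
      else NULL
    },
    modd = {
      if (k == "constant") 0
      else if (divides(1440)) 0
      else NULL
    },
    sd = if (k == "constant") 0 else NULL,
    avg_auc_high = {
      trh <- params$tr_high
      if (is.null(trh)) return(NULL)
      if (k == "constant") max(spec$baseline - trh, 0)
      else if (k == "square_wave" && divides_span(spec)) {
        (max(spec$baseline + A - trh, 0) + max(spec$baseline - A - trh, 0)) / 2
      } else NULL
    },
    avg_auc_low = {
      trl <- params$tr_low
      if (is.null(trl)) return(NULL)
      if (k == "constant") max(trl - spec$baseline, 0)
      else if (k == "square_wave" && divides_span(spec)) {
        (max(trl - spec$baseline - A, 0) + max(trl - spec$baseline + A, 0)) / 2
      } else NULL
    },
    patr = {
      trh <- params$tr_high
      if (is.null(trh)) return(NULL)
      if (k == "constant") 100 * (spec$baseline > trh)
      else if (k == "square_wave" && divides_span(spec)) {
        50 * ((spec$baseline + A > trh) + (spec$baseline - A > trh))
      } else NULL
    },
    pbtr = {
      trl <- params$tr_low
      if (is.null(trl)) return(NULL)
      if (k == "constant") 100 * (spec$baseline < trl)
      else if (k == "square_wave" && divides_span(spec)) {
        50 * ((spec$baseline + A < trl) + (spec$baseline - A < trl))
      } else NULL
    },
    mage_plus = ,
    mage_minus = ,
    mage_avg = {
      me <- if (is.null(params$me)) 45 else params$me
      if (k == "constant") NA_real_
      else if (k == "sawtooth") sawtooth_mage(spec, metric, me)
      else NULL
    },
    NULL
  )
}

# Analytic MAGE of a noise-free sampled triangle wave. The grid samples
# every extremum exactly when period/2 is a whole number of slots; the
# half-open window usually ends between extrema, leaving one trailing
# partial excursion that counts only when its amplitude exceeds me.
sawtooth_mage <- function(spec, metric, me) {
  half <- spec$period / 2
  if (abs(half / spec$interval - round(half / spec$interval)) > 1e-9) {
    return(NULL)   # extrema fall between slots: no exact closed form
  }
  A <- spec$amplitude
  t_end <- (spec$n_slots - 1) * spec$interval
  n_half <- floor(t_end / half)          # complete half-cycles
  if (n_half < 1) {
    return(NULL)
  }
  # full swings alternate up (nadir->peak) first, amplitude 2A each
  dirs <- rep(c("up", "down"), length.out = n_half)
  amps <- rep(2 * A, n_half)
  rem <- t_end - n_half * half
  if (rem > 0) {
    partial <- 4 * A * rem / spec$period   # partial swing off the last extremum
    if (partial > me) {
      dirs <- c(dirs, if (n_half %% 2 == 0) "up" else "down")
      amps <- c(amps, partial)
    }
  }
  counted <- amps > me
  up <- amps[counted & dirs == "up"]
  down <- amps[counted & dirs == "down"]
  mp <- if (length(up)) mean(up) else NA_real_
  mm <- if (length(down)) mean(down) else NA_real_
  switch(metric,
    mage_plus = mp,
    mage_minus = mm,
    mage_avg = {
      d <- c(mp, mm)
      d <- d[!is.na(d)]
      if (length(d)) mean(d) else NA_real_
    }
  )
}

# TRUE when the whole recording is a whole number of periods (so that the
# half/half duty split of the square wave is exact on the grid).
divides_span <- function(spec) {
  span <- spec$duration_hours * 60
  abs(span / spec$period - round(span / spec$period)) < 1e-9 &&
    abs(spec$period / (2 * spec$interval) -
          round(spec$period / (2 * spec$interval))) < 1e-9
}
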