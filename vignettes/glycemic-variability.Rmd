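---
title: "Glycemic variability metrics and the modified MAGE algorithm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Glycemic variability metrics and the modified MAGE algorithm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glyvar)
```

## The problem

Continuous glucose monitoring (CGM) samples interstitial glucose every
five minutes, producing 288 readings per day. Summarizing how *unstable*
glycemia is — not just how high or low — requires a family of
variability metrics, each sensitive to a different time scale:

* **Avg. AUC-H / Avg. AUC-L** — time-averaged exceedance above/below an
  adjustable target range `[TR_L, TR_H]`:
  `(1/T) ∫ (G(t) − TR_H) dt` over `G(t) > TR_H` (and the mirror image
  below `TR_L`). A value of 10 mg/dL means the curve exceeded the upper
  bound by 10 mg/dL on average over the whole observation.
* **PATR / PBTR** — percentage of observed time spent above/below the
  target range.
* **SD** — sample standard deviation of all observed readings.
* **CONGA(n)** — SD of the glucose differences at a lag of `n` hours
  (`D_t = BG_t − BG_{t−n·60min}`, `sqrt(Σ(D_t − D̄)² / (k−1))`);
  short-term, within-day variability. The conventional order is `n = 1`.
* **MODD** — mean absolute difference between readings exactly 1,440 min
  apart (`Σ|BG_t − BG_{t−1440}| / k`); between-day variability.
* **MAGE** — mean amplitude of glycemic excursions: the average size of
  nadir-to-peak (MAGE+) and peak-to-nadir (MAGE−) swings larger than a
  *meaningful excursion* threshold ν, with MAGE avg. their mean and the
  excursion frequency (EF) their count.

This package computes all of the above from either CareLink-style
exports or generic two-column CSV files, after aligning the readings to
a fixed grid and filling short sensor dropouts.

## Grid model and gap interpolation

All metrics are computed on a fixed grid (default 5 min). The grid is
anchored at the first sample's timestamp rounded *down* to a whole
interval — deterministic, and consistent with the fixed epochs of CGM
devices — and each sample is assigned to its nearest slot (two samples
in one slot indicate super-nominal sampling and are rejected).

Missing slots are filled by **bounded linear interpolation**: a run of
consecutive missing slots is filled only when it is bounded by observed
slots on both sides and no longer than `max_gap` slots (default **21**,
i.e. 1 h 45 min of signal). Leading and trailing runs are never
extrapolated, and longer runs stay missing — metrics then exclude them
slotwise (AUC, PATR/PBTR, SD) or pairwise (CONGA, MODD), and MAGE
analyses the observed segments independently, pooling the amplitude
lists. Interpolation happens after window selection, never across
window boundaries.

Two properties are worth stating because the tests rely on them: every
interpolated value lies within the closed interval of its two bounding
observations (no invented extrema), and the operation is idempotent.
Interpolation tends to *understate* variability — a straight line is the
least variable path between two points — which is why the report always
carries the number of interpolated points next to the total.

## The modified MAGE algorithm

MAGE is the only metric without a closed form; it is computed by a
turning-point procedure in the Baghurst style with three departures.

1. **Turning points.** All strict local extrema plus the endpoints, with
   plateaus collapsed to their first slot, giving an alternating
   peak/nadir sequence.
2. **Pruning to a fixed point.** Three deletion passes repeat until
   nothing changes:
   * a point whose adjacent excursions are both ≤ ν is deleted, and its
     two like-kind neighbours merge keeping the more extreme one (ties
     keep the earlier) — *unless* the point is the centre of a **W/M
     pattern**: strictly less extreme than both like-kind neighbours
     (a peak lower than the adjacent peaks, a nadir higher than the
     adjacent nadirs). Such centres are retained throughout — this is
     the modification; the original procedure deletes them;
   * a sub-ν excursion whose bounding points each have a countable
     excursion on their other side loses both bounding points (the
     small wiggle inside a large swing);
   * an endpoint whose single excursion is ≤ ν is dropped, unless it
     props up a W/M centre as its like-kind neighbour.
3. **Start-point relocation.** When neither `G(t)MAX − G(t₁) > ν` nor
   `G(t₁) − G(t)MIN > ν` although the curve does contain meaningful
   excursions, no excursion is reachable from the first sample; the
   start moves to the global extremum. When both the maximum and the
   minimum qualify, the one occurring *first* is chosen — the
   documented reading of an ambiguity the method leaves open.
4. **Backtrack recheck.** Once the first meaningful excursion is found,
   the stretch between the segment origin and that excursion's origin is
   re-scanned with the same machinery; any excursion found there was
   skipped by a relocated start and is prepended in temporal order.

MAGE+ / MAGE− are the means of the retained up/down amplitudes
exceeding ν; MAGE avg. averages the defined sides (equalling the
one-sided value when only one direction has countable excursions); EF
counts countable excursions only — sub-ν excursions surviving through
W/M retention are excluded from EF by design. When the final curve
still contains such a sub-ν excursion the report sets
`alert_visual_analysis` and emits, verbatim,
*"Visual analysis should be performed, see User Documentation"*.

### What W/M retention does — and does not — optimize

Retention is a fidelity choice, not an optimization. Two measurable
consequences, both exercised in the test suite:

* retention can keep two same-direction countable excursions separated
  only by a sub-ν wiggle, so the excursion count can differ in either
  direction from the *maximal alternating decomposition* (the largest
  possible chain of alternating >ν swings, computable by dynamic
  programming on short series);
* independently of retention, a large swing built entirely of sub-ν
  steps ("staircase") can collapse during pruning, because its top is a
  point with sub-ν excursions on both sides.

For these reasons the dynamic program is used in the tests only as a
bound (the unmodified variant's count never exceeds it; no variant may
report an excursion when no >ν swing exists), while exactness of the
implementation is established against an independent naive
re-implementation of the stated rules on 100 seeded fixtures.

## Tunable parameters

| Parameter | Default | Unit | Meaning |
|---|---|---|---|
| `tr_low`, `tr_high` | none (user-set) | mg/dL | target range for AUC and time-in-range metrics |
| `me` (ν) | 45 | mg/dL | meaningful-excursion threshold for MAGE; the classical 1-SD rule is deliberately not used |
| `conga_n` | 1 | hours | CONGA lag |
| `interval` | 5 | min | grid spacing |
| `max_gap` | 21 | slots | longest missing run that may be interpolated |

Thresholds are strict (`G > TR_H`, `G < TR_L`); a reading exactly on a
bound counts as in range. SD and CONGA use the `N − 1` denominator.
All internal computation is in mg/dL (mmol/L inputs are converted with
the fixed factor 18.0182 mg/dL per mmol/L, the molar mass of glucose
divided by ten); no rounding is applied at conversion.

## The synthetic generator as test bed

`fixture_spec()` / `generate_series()` emulate exactly the input class
the metrics target: a 5-minute-grid series, one to two days long,
around a normoglycemic baseline (default 100 mg/dL), with configurable
waveforms (constant, ramp, sinusoid, triangle "sawtooth", square wave,
reflected Gaussian random walk), seeded Gaussian sensor noise and
injected missing runs. For analytic waveforms `known_answer()` returns
the exact metric value the pipeline must reproduce — including the
trailing partial excursion a half-open window leaves on a sawtooth —
so every metric is checkable to 1e-9 without any real recording.

What the generator does **not** emulate: calibration step artifacts
(sudden jumps when the sensor is re-referenced), sensor drift and
compression lows, physiologic meal/insulin dynamics, and non-Gaussian
noise. Passing tests therefore demonstrate correctness of the
*computation*, not robustness to every artifact of real sensor data;
calibration steps in particular can inflate variability in ways no
metric here corrects for.

Problem sizes used throughout the tests are chosen to be both
representative and quick: 48-hour windows (576 slots) for the
closed-form metrics, 50 seeded random-walk days for the metric oracles,
and 100 fixtures of 20–40 slots for the MAGE oracle, where exhaustive
reasoning about turning points is tractable.

## Numerical and degenerate-input choices

* Metrics that are undefined — MODD on ≤ 24 h of data, CONGA with fewer
  than two usable pairs, SD with fewer than two observations, MAGE with
  no countable excursion — are `NA` in R and `null` in JSON, never 0.
* Duplicate timestamps with identical glucose deduplicate silently;
  conflicting duplicates are an error.
* Pruning ties (two equal like-kind extremes) keep the earlier point.
* A constant series has no turning points; series shorter than three
  slots yield none.
* Fixture generation saves and restores the caller's RNG state.

## Limitations

The excursion frequency counts only countable excursions; whether
sub-threshold excursions retained through W/M patterns should count is
left open by the method and excluded here. Binary `.xls` CareLink files
are not parsed — re-export as CSV. The CareLink column aliases cover
the common sensor-glucose headers but unusual dialects should go
through `read_generic_csv()` with explicit column names. No smoothing,
outlier rejection or calibration correction is applied.
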