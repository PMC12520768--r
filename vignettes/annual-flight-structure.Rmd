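---
title: "Detecting and segmenting the annual migratory flight activity of a songbird"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and segmenting the annual migratory flight activity of a songbird}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement model

A leg-mounted multisensor logger records one accelerometer sample every
5 minutes, each consisting of five brief subsamples a few seconds apart.
The activity score of a sample is the number of subsamples whose
acceleration varied by more than a quarter g — an integer 0 (rest) to 5
(continuous motion). Sustained flapping flight produces scores of 4 or 5;
foraging, preening and territorial behaviour produce intermittent motion
scoring 1–3. `score_sample()` implements exactly this counting rule, and an
`activity_series` is one bird-year of scores on a strict 5-minute UTC grid,
with data gaps carried in-band as missing scores so that hourly data
completeness stays computable.

## Flight detection

A migratory flight bout is a maximal run of consecutive samples scoring at
least 4 that lasts longer than 30 minutes. On a 5-minute grid the smallest
such run is 7 samples (35 min), which is the `min_run_samples` default in
`detection_config()`. Two choices deserve comment:

* **Runs, not hourly bins.** The qualifying rule is sometimes phrased as
  "at least 7 qualifying scores per hour", but binning by clock hour would
  make detection depend on where the hour boundaries happen to fall. We
  detect maximal *consecutive* runs; the 7-sample minimum is equivalent for
  any run contained in an hour and strictly more faithful to "continuous
  flight" for longer ones.
* **Strict runs.** A single sub-threshold or missing sample terminates a
  run; there is no gap tolerance. Whether brief dips inside a true flight
  should be bridged is unknowable from the data alone; instead, multiple
  runs during one night are reunified at the night level (below), and the
  generator's noise mode (`noise_rate`) lets a user quantify the
  sensitivity of detection to score corruption.

Nocturnal flights span midnight, so flights are attributed to *nights*
rather than civil dates: the night keyed by date *d* runs from local solar
noon of *d* (12:00 UTC − longitude/15 h) to the next local solar noon.
These windows tile time exactly, and any flight departing after sunset and
ending before the next sunrise falls inside one window. The axis convention
(UTC, CET or solar time) of the original actograms is not recorded
anywhere; solar-noon windows at a reference longitude (default 12.33° E,
the breeding site) are our choice and are documented as such. All runs of
one night merge into a single `NightFlight`; its duration is the sum of
qualifying samples across parts, in 5-minute quanta, and its departure is
the first qualifying sample.

## Segmentation of the annual cycle

`segment_migration()` applies four rules in sequence:

1. **Clustering** (`cluster_nights()`): flight nights separated by more
   than `gap_threshold_days` (default 9 days, strictly greater) belong to
   different clusters.
2. **Classification** (`classify_annual()`): clusters with fewer than
   `min_segment_nights` (default 3) flight nights are set aside as *odd
   flights*; the *winter interval* is the longest gap between the
   remaining qualifying clusters — computed over qualifying clusters only,
   so an odd mid-winter flight cannot bisect winter. Qualifying clusters
   before winter are autumn segments 1..k (a warning is recorded when
   k ≠ 3, rather than force-merging clusters); those after winter are
   pooled for spring.
3. **Spring split** (`split_spring()`): the boundary between the first
   spring segment and the rest is the single longest inter-night gap in
   the pooled spring flights (earliest on ties) — the longest spring
   stopover, at the Horn of Africa in this study system. Pooling means the
   rule is applied even when the >9-day rule already produced several
   spring clusters.
4. **Zugknick split** (`zugknick_split()`): the last two spring segments
   are usually not separated by any stopover — the birds fly every
   consecutive night from the Horn of Africa to the breeding grounds — but
   by an abrupt westward course change. At more westerly longitudes local
   sunset, and hence nocturnal departure, is later in UTC; the rule takes
   the median departure clock time of the first `zugknick_baseline_nights`
   (default 2) nights after the longest spring stopover as baseline, and
   the first night departing more than `zugknick_delay_h` (default 1.5 h)
   later starts the final segment. All later nights stay in the final
   segment even if departures recede (nights shorten northwards). If no
   night crosses the threshold the spring remainder stays one segment,
   with a warning.

The choice `min_segment_nights = 3` discriminates segments from odd
flights in a way the >9-day isolation rule alone cannot: the smallest
observed segment averages ~8 flights while odd flights average ~3 per bird
scattered over four widely separated phases, so a 3-night minimum is
conservative in both directions. Segment duration is the calendar-day
difference between the first flight's night and the date on which the last
flight *ends* (a flight landing after midnight extends its segment by a
day; a 1-night segment has duration 0).

Every detected flight receives exactly one label — a segment number 1–6 or
"odd" — and odd flights carry the stationary phase they fall in
(pre-migration, the south-east-European or Sahel autumn stopovers, or
winter), assigned from their position relative to the adjacent segments.

## Cohort statistics

`cohort_table()` reproduces the study-style summary: per segment and per
season, the start/end dates, flight counts, segment durations and total
flight hours as mean ± sample s.d. with each cell's own n of birds, plus
per-flight duration statistics pooled over flights and coefficients of
variation (100 · s.d./mean). Season rows pool segments 1–3 and 4–6; date
statistics are computed on the continuous date scale (all dates of a
bird-year fall in one annual window, so circularity never arises). Odd
flights are excluded throughout and summarized separately by
`odd_summary()`, including their share of annual flight hours and flights.

`levene_test()` is the Levene/Brown–Forsythe heterogeneity test — a
one-way ANOVA on absolute deviations from the group centre. The default
centre is the group median (the default of the `car` package, which also
provides the computation here); the original mean-centred Levene is
available by flag. A 0/0 statistic from groups with identical nonzero
absolute deviations is reported as perfect homogeneity (W = 0, p = 1);
groups with zero spread outright are refused as undefined. The test suite
checks the implementation against a direct evaluation of the W formula at
10⁻¹⁰ tolerance.

## Actograms

`actogram_grid()` aggregates a series into hourly cells: the mean of the
present scores, and a class — `none` (mean 0), `high`, else `medium`, with
`incomplete` (1–11 of 12 samples missing) and `missing` (all 12) taking
precedence. The `high` rule is deliberately the detection rule (≥ 7
qualifying samples in the hour), so the figure can never disagree with the
analysis; the original figures' green/black cut is not stated anywhere and
this reuse is our convention. One caveat follows from hour binning: a
flight straddling two clock hours can leave up to 6 qualifying samples on
each side, so the count of high cells can fall short of the detected
flight hours by at most one hour per flight — the property suite tests
exactly that sharp bound. `render_actogram()` writes the classic
double-plotted layout (rows of two consecutive days, the second day
repeated as the first half of the next row) as a deterministic PNG with
white/green/black cells and yellow/red quality flags.

## The synthetic generator

`simulate_itinerary()` plants a full annual itinerary; `emit_activity()`
renders it as a score series. The defaults encode the study conditions —
the per-segment phenology, flight counts, per-flight duration
distributions, per-segment total flight hours, stopover durations, and
odd-flight rates of the 15-bird red-backed shrike cohort — and are not
meant to be tuned per analysis.

Design of the generator, where choices were genuinely open:

* **Distribution shapes.** The cohort descriptives give only mean ± s.d.;
  we use normals for dates, counts and stopovers, and truncated normals on
  (1 h, observed max] for per-flight durations. Because that truncation is
  asymmetric, drawing around the printed mean would bias the realized mean;
  the location parameter is therefore moment-matched (`tn_location()`) so
  the truncated draw reproduces the printed mean exactly.
* **Chained phenology.** Segment 1's start is drawn around its anchor
  date; every later segment starts after the previous segment's last
  flight plus the drawn stopover. This reproduces the stopover *and*
  start-date means simultaneously, at the cost of compounding start-date
  variance down the year (real birds re-synchronize; independent draws of
  every start date would instead contradict the stopover durations). The
  acceptance quantities use means, not date variances.
* **Per-segment flight-hour budgets.** Per-bird segment totals in the
  study vary far less than independently drawn per-flight durations would
  produce (spring CV ≈ 6 %). The generator therefore draws each segment's
  *total* from its observed mean ± s.d. and uses the truncated-normal
  draws only as the within-segment shape, rescaling them to the budget
  under per-night caps: each flight is capped by
  min(observed per-flight max, sunset-to-sunrise window), and hours
  clipped on short nights are redistributed to the segment's other nights.
  This mirrors a flight-hour budget under nocturnal constraints and keeps
  both the totals' means and dispersions faithful.
* **Night scheduling.** Flight nights inside autumn segments and segment 4
  are spaced with inter-night differences of 1–3 days (the within-segment
  stopover pattern is not reported anywhere; 1–3 days is our assumption,
  exposed as `max_intra_gap_days`); segments 5 and 6 fly strictly
  consecutive nights. Departures are local sunset plus 0–40 min of
  uniform jitter; odd flights are instead initiated mid-night, their
  defining behavioural signature. All flights end by local sunrise (a
  one-per-bird prolonged barrier-crossing flight into daytime is available
  behind `prolonged_flights`, off by default).
* **Well-posedness clamps.** So that the planted truth is unambiguous for
  the segmentation rules, autumn stopovers are clamped to ≥ 10 days, the
  Horn-of-Africa stop to ≥ 4 days (always the longest spring gap), the
  segment-5/6 stop to 0–3 days, per-segment flight counts to ≥ 3, and odd
  flights to ≥ 10 days from every segment and from each other. Winter is
  clamped to ≥ 60 days.
* **Waypoints and the planted course change.** Nightly departure positions
  are interpolated along a plausible loop (Denmark → SE Europe → Sahel →
  SW Africa → Horn of Africa → Middle East → Denmark); only plausibility
  matters — positions drive night length and departure time, not any
  geographic analysis. Segment 5 crosses Arabia due north at constant
  longitude, so its departure drift stays well under the 1.5 h threshold,
  and segment 6 begins from a waypoint well to the west (38° N, 23° E):
  the Zugknick appears as a planted longitude shift whose ~2 h departure
  delay is *emergent* from solar geometry, never written into the
  departure times themselves. The detector is thereby tested against the
  signal, not against its own definition.
* **Solar geometry.** `sun_events()` implements the standard NOAA
  solar-position equations (civil sunrise/sunset at zenith 90.833°),
  accurate to a few minutes at the latitudes involved; polar latitudes
  (|lat| > 66°) are refused explicitly.

Emission is exact by construction in the default noise-free mode: planted
flight minutes score 4–5, non-flight night samples 0, and daylight samples
1–3 under a bimodal diel profile, so no non-flight sample ever qualifies
and detection recovers every planted flight with its 5-minute-quantized
duration exactly. Durations are quantized at planting time (a 6.0 h flight
is exactly 72 samples), which is what makes exact recovery a meaningful
test rather than a tolerance game. Optional noise replaces samples with
uniform random scores at a configured rate; optional missing-data mode
blanks whole hours.

What the generator deliberately does **not** emulate: weather and wind,
fuel-deposition dynamics, barometric pressure or light channels,
second-year journeys, within-individual behavioural correlation beyond the
segment budgets, or realistic inter-flight gap patterns beyond the 1–3-day
assumption. Passing the recovery suite therefore demonstrates that the
pipeline's rules are mutually consistent and recover a *known* structured
itinerary through an exact emission model — it does not certify detection
performance on noisy field data, for which the noise and missing-data
modes provide sensitivity handles but no ground truth.

## Problem sizes and reproducibility

The validation suite and the acceptance script use the study's cohort
size: 15 birds, one annual cycle each (~100 000 samples per bird), which
simulates and processes in a few seconds. All randomness flows from a
single integer seed through derived per-bird seeds, so identical
configurations and seeds give byte-identical logger files. The test
suite's fixed seed is 42 by convention; `scripts/acceptance.R` takes its
seed on the command line.

## Known limitations

* Real loggers drift in clock and die mid-year; the reader normalizes
  gaps, but no clock-drift correction is attempted.
* A bird whose autumn produces ≠ 3 qualifying clusters (e.g. a true
  segment interrupted by a >9-day pause) is numbered in date order with a
  warning — there is no rule to force-merge, and inventing one would be
  guesswork.
* The Zugknick baseline ("the departure time for the first nocturnal
  flights" after the Horn of Africa) is ambiguous in prose; we use the
  median of the first 2 nights, configurable via
  `zugknick_baseline_nights`.
* Departure clock times are compared on the UTC day scale; the rule as
  stated would need care near the antimeridian, far outside this system's
  geography.
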