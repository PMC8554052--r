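---
title: "Feeding-rhythm analysis from tube position traces: model, calibration and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Feeding-rhythm analysis from tube position traces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flyfae)
```

## The behavioral model

A fly housed in a 65-mm glass tube with food at one end does not remain on
the food; it shuttles between the food end and the rest of the tube. With
the position of the fly's barycenter sampled at 1 frame per second and
projected onto the tube axis, feeding-related behavior appears as
excursions to high coordinates (our convention: 0 px at the cotton end,
increasing toward the food).

The package's unit of analysis is the **food-approaching event (FAE)**: a
maximal run of consecutive samples at or beyond the *feeding-zone
boundary*, one body length below the food surface. Three indices summarise
events in any zeitgeber-time (ZT) interval:

* FAEn — the number of events whose *onset* falls in the interval;
* FAErt — the summed duration of those events (seconds; at 1 fps a
  sample is a second);
* FAErt/n — FAErt divided by FAEn, the mean visit length.

The model's assumptions are deliberately weak: a single fly per tube, a
single food end, and a fixed geometry per fly-day. Nothing about the
dynamics between visits is modelled; only zone membership matters.

## Geometry: food surface and feeding zone

The food surface moves slightly from tube to tube (and, as food dries,
from day to day), so it is estimated per fly and per 24-h day.

* `detect_food_surface(method = "max")` — the default — takes the
  farthest coordinate the fly reached that day. It is exact whenever the
  fly touches the food at least once and tracking is clean.
* `detect_food_surface(method = "peak_mode")` is a robust variant for
  traces with tracking glitches: it histograms the day's positions in
  1-px bins and returns the highest-coordinate local maximum supported by
  at least `min_peak_count` samples (default 5). A single corrupted
  sample beyond the food cannot become the surface, because a real visit
  occupies at least several seconds of the day; the default of 5 samples
  encodes exactly that.

The zone boundary is `food_surface_px − body_length_px`. Body length
defaults to 11 px (males); use 12 px for females — at the supported
magnification one body length is 11–12 px. Zone membership is
**inclusive** (`position ≥ boundary`): a fly touching the boundary is in
the zone. This choice is arbitrary at the precision of a pixel but is
fixed and documented so that results are bit-reproducible.

## Segmentation rules

`segment_events()` applies three rules beyond plain run detection:

* **Day boundaries.** Geometry is per-day, so a run crossing ZT 0 is
  split and each part assigned to its own day. Events are then binned
  into hours/windows by onset, which keeps FAEn additive over any
  partition of the day.
* **Missing samples.** Dropped frames are carried as missing from ingest
  (never interpolated). The default `"break"` policy ends a run at a
  missing sample — presence in the zone is never invented. A `"bridge"`
  policy tolerates up to `bridge_k` consecutive missing samples flanked
  by in-zone samples, counting them toward the duration; it exists for
  recordings with brief tracker dropouts, and its semantics are tested
  against hand-built cases.
* **Durations are integer seconds.** Sub-second timing is outside the
  resolution of a 1-fps recording.

Fly-days whose first second of ZT 0 reads coordinate 0 indicate a fly
parked at the cotton end at the day change, which the upstream tracker
reports as a degenerate trace; `drop_zeroed_day_traces()` excludes those
fly-days (and only those) from every downstream computation.

## The duration band filter and its calibration

Visits shorter than a few seconds are dominated by exploration without
feeding; immobile episodes of five minutes or more meet the standard fly
sleep definition. Both ends are handled by one band filter: an event is
retained iff `low ≤ duration ≤ high`, **both edges inclusive**, with
defaults 7 s and 300 s.

The low edge is an empirical calibration, not a constant of nature. The
calibration procedure shipped here is:

1. score visits in high-magnification video as *feeding* (two or more
   proboscis extensions during the visit) or *no-feeding*, and attach the
   labels to detected events with `merge_annotations()` (onset tolerance
   ±1 s, because the scoring videos run at a different frame rate);
2. tabulate the labeled visits by duration bin (`proportion_table()`,
   default bins 1–3, 4–6, 7–9, ≥ 10 s);
3. sweep candidate low cut-offs (`sweep_thresholds()`, default grid
   2–9 s) and read off, per threshold, the retained fraction of feeding
   and no-feeding events and residence time.

The tool deliberately has no automatic threshold chooser: the selection
criterion — eliminate as much no-feeding signal as possible while keeping
the feeding signal — is qualitative, and the sweep report is exactly the
evidence a user needs to make it. The shipped calibration counts
(`inst/extdata/`) record the labeled totals of such a calibration in
males (200 feeding, 351 no-feeding events across 551; five ZT windows
totalling 1,185 events), and the package's validation checks their
arithmetic identities.

## Hourly curves, windows and group statistics

`hourly_summarize()` bins retained events by onset into the 24 ZT hours
(half-open intervals), per fly-day. `window_summarize()` does the same
for named windows; the canonical four are ZT 0–2 (morning peak), 3–11
(day), 12–14 (evening peak) and 15–23 (night), which partition the day.

`group_aggregate()` first averages days within each fly, then computes
mean and SEM (sample SD / √n) across flies — each fly is one independent
unit, and the group *n* counts flies, not fly-days. FAErt/n for an hour
with no events is reported as 0 and flagged undefined; undefined cells
are excluded from fly-level day averages and hence from group means of
the ratio. (For count and time metrics a zero is a real observation and
is never excluded.) Under constant darkness, hours keep the subjective ZT
inherited from prior entrainment.

`compare_groups()` wraps the standard routines (`t.test`, `aov`,
`TukeyHSD`) with the conventional significance levels
(0.05/0.01/0.001/0.0001); the package's contribution is the result
schema, not the numerics. The t test defaults to the classical
equal-variance form.

## The synthetic-behavior generator

`simulate_cohort()` provides ground truth for every other module. Its
defaults *are* the regime the analysis targets:

* **Visit rate**: an inhomogeneous Poisson profile with morning
  (ZT 0–1) and evening (ZT 12–13) peaks of 12 visits/h over a 3–4
  visits/h baseline — about 120 visits per fly-day, a realistic unfiltered
  approach rate for a wild-type male. `ld_mode = "mutant_flat"` replaces
  the profile with its daily mean, emulating an arrhythmic clock mutant
  under constant darkness.
* **Durations**: feeding visits are log-normal (median 15 s,
  `sdlog = 0.8`), capped at 250 s — the longest manually scored visit on
  record; no-feeding visits are geometric-like (`1 + rgeom(0.4)`, median
  2 s). Under these defaults ≥ 90% of no-feeding visits are shorter than
  7 s and ≥ 70% of feeding visits last 7 s or longer, mirroring the
  empirical separation that motivates the 7-s cut-off. The feeding
  fraction of visits is 0.36 (the labeled feeding share).
* **Placement**: each visit is placed uniformly within its hour,
  rejected and redrawn if it would come within 1 s of another visit (so
  the segmenter can separate neighbours), and realised as an in-zone run
  of exactly the drawn duration with at least one sample touching the
  food surface. Between visits the fly performs a reflected Gaussian
  random walk (step SD 6 px) strictly below the zone boundary.

Identical seeds give bit-identical traces and ground truth.
`simulate_daily_totals()` draws per-fly daily filtered-FAErt totals from
the same rate and duration models without trace synthesis, for
replicate-heavy studies of the statistics layer.
`render_frames()` draws each sample as a dark Gaussian blob on a bright
background for testing the centroid tracker.

What the generator does *not* emulate: tracker noise correlated in time,
position-dependent dwell dynamics at the food surface, drifting food
surfaces within a day, egg-laying excursions, or fly-to-fly heterogeneity
in overall visit rate. Passing end-to-end tests therefore demonstrate
that the pipeline recovers what it is defined to recover — not that real
traces are this clean. On real data the deliverables remain the filter
calibration curves and the index tables, whose correctness is established
by the oracle-equivalence and property tests, not by the simulator.

## The frame tracker

`extract_positions_from_frames()` is minimal by design: per-pixel
temporal-median background, subtraction, thresholding, and an
intensity-weighted centroid projected onto the tube axis. One wrinkle: a
fly that never moves would be absorbed into its own temporal median, so
the background estimate is floored at the global median intensity of the
stack. This handles the static-fly case at the cost of assuming a fairly
uniform bright background — true for the supported backlit-tube imaging,
not for arbitrary scenes. Sub-threshold residuals carry no weight in the
centroid, so moderate pixel noise does not drag positions toward the
frame centre.

## Numerical and validation choices

* **Oracle equivalence.** Every aggregation path (segmentation,
  proportion tables, sweeps, hourly summaries) is tested against an
  independent brute-force loop on seeded random inputs (100 cases each).
* **End-to-end recovery.** A 20-fly × 2-day simulated cohort (the
  package's standard validation size — large enough for stable group
  curves, small enough to re-run routinely) is re-detected with 100%
  recall, zero duration error, and per-fly-day filtered FAErt within
  ±15% of the programmed feeding time; the group FAErt curve's morning
  and evening maxima fall in the programmed peak blocks.
* **Flat-profile check.** For the clock-mutant mode, "no peak" is
  operationalised per hour: over 100 seeded replicates, each hour's group
  mean exceeds the daily mean by more than 2 SEM in at most 5% of
  replicates. The per-replicate alternative ("no hour exceeds, in ≥ 95%
  of replicates") is not a property any flat process has — with 24
  simultaneous ~2-SEM comparisons the family-wise exceedance is ~40% —
  so the per-hour formulation is the statistically meaningful reading,
  and it is the one implemented.
* **Type-I sanity.** One-way ANOVA on three equal-mean groups of
  simulated per-fly totals rejects at 4–5% over 1,000 replicates, and a
  t test on identical samples returns exactly t = 0, p = 1.
* **Ties and degenerate inputs.** `proportion_table()` and
  `sweep_thresholds()` refuse unlabeled-only input; geometry estimation
  refuses all-missing days and fully excluded flies; FAErt/n at FAEn = 0
  is 0-with-flag, never NaN; SEM for n = 1 is NA, never 0.

## Known limitations

* Single-food-end tubes only; the data model does not preclude multi-end
  chambers but no module handles them.
* The tracker assumes one dark fly on a bright background inside the ROI;
  it is a fixture-grade tool, not a replacement for a production tracker.
* The band filter is duration-only; it cannot distinguish a long
  no-feeding visit from feeding, and the calibration data show a small
  minority of such visits survive any duration cut-off.
* No periodogram or rhythm-strength statistics are computed; the package
  stops at curves, windows and group comparisons.
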