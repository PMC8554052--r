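# flyfae

Quantifying feeding rhythms of individually housed *Drosophila* from
one-frame-per-second video-tracking position traces.

## The problem and the method

Flies in glass-tube activity monitors do not sit on their food: they
approach it, eat, leave and return. If a fly's 1-D position along the tube
is sampled once per second, those visits are visible as excursions to the
food end of the tube. `flyfae` turns such traces into **food-approaching
events (FAE)** and summarises them into three circadian feeding indices:

- **FAEn** — the number of FAE in an interval (a visit count),
- **FAErt** — their summed residence time in seconds,
- **FAErt/n** — the mean residence time per visit (FAErt ÷ FAEn).

An FAE is a maximal run of consecutive seconds the fly spends inside the
*feeding zone*: the region within one body length (11 px for males, 12 px
for females at the supported optics) of the food surface. The food surface
itself is estimated per fly and per 24-h day as the farthest coordinate the
fly reached that day (with a histogram-peak variant for glitchy traces).
Coordinates are pixels, 0 at the cotton end, increasing toward the food.

Short visits are dominated by exploration without feeding, and very long
immobile episodes at the food end shade into sleep (≥ 5 min of quiescence
is the standard fly sleep definition). Events are therefore passed through
a **duration band filter**: an event is retained iff

```
low ≤ duration ≤ high        (both edges inclusive; default 7–300 s)
```

The low edge is calibrated from high-magnification recordings in which
each visit was manually scored as *feeding* (two or more proboscis
extensions) or *no-feeding*: `sweep_thresholds()` reports, for each
candidate cut-off, the retained fraction of feeding and no-feeding events
and residence time, and `proportion_table()` gives the duration-binned
composition of the labeled visits. Retained events are aggregated by onset
time into hourly curves, canonical ZT windows (ZT 0–2, 3–11, 12–14,
15–23), day/night totals and group mean ± SEM curves, with standard group
comparisons (t test, one/two-way ANOVA + Tukey HSD).

A synthetic-behavior simulator (`simulate_cohort()`) generates 1-fps tube
traces with a programmable bimodal circadian visit-rate profile, distinct
feeding / no-feeding visit-duration distributions and exact ground truth,
so the whole pipeline can be validated end to end; `render_frames()` plus
the minimal centroid tracker (`extract_positions_from_frames()`) close the
loop from pixels to indices.

## Worked example

```r
library(flyfae)

cfg <- simulation_config(seed = 11, n_flies = 6, n_days = 2)
sim <- simulate_cohort(cfg)

tr   <- sim$traces[[1]]
geom <- food_geometry(tr, body_length_px = 11)
print(geom)
ev  <- segment_events(tr, geom)
cat("detected events:", nrow(ev), "\n")
ev  <- apply_band_filter(ev, event_filter(7, 300))
cat("retained by 7-300 s band:", sum(ev$retained), "\n")
idx <- compute_indices(ev, interval = c(0, 3 * 3600))
cat(sprintf("ZT0-2: FAEn=%d FAErt=%d s FAErt/n=%.1f s\n",
            idx$faen, idx$faert_s, idx$faert_per_event))
```

which prints (per-day geometry, then the morning-window indices):

```
  day_index food_surface_px zone_boundary_px
1         1             250              239
2         2             250              239
detected events: 237
retained by 7-300 s band: 82
ZT0-2: FAEn=21 FAErt=549 s FAErt/n=26.1 s
```

237 detected visits collapse to 82 after the band filter — the short
exploratory visits are gone. The fly made 21 retained visits in the
morning window (ZT 0–2), spending 549 s at the food, 26.1 s per visit.
Aggregating all six flies into a group curve:

```r
all_ev <- apply_band_filter(do.call(rbind, lapply(sim$traces, function(t)
  segment_events(t, food_geometry(t, 11)))), event_filter(7, 300))
curve <- group_aggregate(hourly_summarize(all_ev))
curve[curve$metric == "faert_s" & curve$hour %in% c(0, 6, 12), ]
```

```
 group hour  metric      mean       sem n
   all    0 faert_s 118.16667 36.170584 6
   all    6 faert_s  22.58333  6.262876 6
   all   12 faert_s  90.91667 13.229649 6
```

The programmed double-peak feeding rhythm is visible: mean residence time
per hour is high at ZT 0 and ZT 12 and low at midday, with SEM across the
6 flies.

## Command line

A thin front end over the same functions lives in `inst/cli/flyfae`:

```sh
flyfae simulate --out-dir sim --seed 1
flyfae detect   --positions sim/positions.csv --out-dir det --sex male
flyfae filter   --events det/FeedingPDF.csv --out-dir fil --low 7 --high 300
flyfae rhythm   --events fil/FeedingPDF.csv --out-dir rhy
flyfae sweep    --events det/FeedingPDF.csv --annotations sim/truth.csv \
                --out-dir swp --thresholds 2:9
```

Stages compose through files (`FeedingPDF.csv` — one row per event;
`Activity.csv` / `Feeding.csv` — hourly FAEn / FAErt per fly-day), each
output directory carries a `manifest.json` with counts and a config hash,
and `--no-cutoff` reproduces unfiltered FAEn-style curves.

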