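# scenefam

Scene-familiarity visual navigation over aerial landscapes, in R.

Insect navigation research has long proposed that a route can be retraced
without a map or sequential memory: store the views seen during training,
then simply keep moving toward whatever looks most *familiar*. `scenefam`
implements and instruments this idea for a downward-looking aerial agent on
large grayscale rasters — the kind of imagery a satellite map tile provides —
for researchers in computational neuroethology, bio-inspired robotics, and
anyone who wants a compact, fully seeded testbed for view-based homing.

## What it computes

The core statistic is the image difference score between two equally
processed views *a*, *b*:

```
d(a, b) = Σ_{p ∈ circular mask} | a_p − b_p |
```

summed over quantized gray levels; low difference = high familiarity. On top
of it the package provides:

* **A low-resolution beam sensor** (`process_view`): crop → rotate to
  heading → per-scene histogram equalization → block-mean downsampling
  (10×10 … 80×80) → gray-level quantization (2/10/100 levels) → circular
  field-of-view mask. `beam_width_deg(100, 250)` = 22.6° — a 100 m patch
  seen from 250 m.
* **Landscape information analytics**: all-pairs difference topography over
  a sample grid (`difference_topography`), familiarity "volcano" surfaces
  around focal scenes (`volcano`), rotational image difference functions
  (`ridf`) as a visual compass, and the p50 catchment summary
  (`p50_summary`, `averaged_region_stats`).
* **Route learning** (`interpolate_path`, `widen_corridor`, `build_memory`):
  a dense training path with per-point travel bearings, widened by one scene
  spacing on each side, each view stored rotated to its bearing.
* **An arc-scan agent** (`recapitulate`): candidates on a 40 m arc ahead of
  the current heading, sampled center-out alternating left/right, each
  matched over all rotations against the whole memory bank; the first
  candidate under a 20%-of-mean familiarity threshold is taken, the next
  scan extends the chosen chord. Plus the summed departure-from-route metric
  (`departure_metric`).
* **Seeded synthetic landscapes** (`make_landscape`) in three information
  regimes — near-featureless water, sparse blobs on smooth ground, dense
  urban-like texture — and canonical routes (`make_route`: straight,
  S-curve, square spiral, self-crossing loop), so nothing needs downloading.
* **An experiment harness** (`run_experiment`) sweeping sensor resolution ×
  pixel depth × regime × seed, one recapitulation per cell.

## Worked example

```r
library(scenefam)

# a seeded, urban-like 600 x 600 m landscape at 1 m/px
land <- make_landscape(terrain_spec("high", size_px = 600, seed = 1))

# a 40 x 40, 10-gray-level sensor over an 80 m window
cfg <- sensor_config(window_px = 80, out_res = 40, gray_levels = 10)

# how localizable is a scene here? volcano + p50 catchment
vol <- volcano(land, position(300, 300), k = 10, cfg, spacing_px = 5)
p50_summary(vol)
#> <scenefam_p50> difference 1814.0 at 3.95 m

# learn an S-shaped route, then release the agent at its start
route <- widen_corridor(interpolate_path(make_route("s_curve", land, 80), 5),
                        land = land, window_px = 80)
mem <- build_memory(land, route, cfg)
mem
#> <scenefam_memory> 459 stored views (1264 px each), route 734 m

rec <- recapitulate(land, route$path_points[1, ], mem,
                    agent_config(max_steps = 60))
rec
#> <scenefam_recap> reached_goal after 37 step(s)
departure_metric(rec, route, 1) / nrow(rec$steps)
#> [1] 5.2   # meters of departure per 20 m step
```

The agent retraces the 734 m S-curve in 37 twenty-meter steps, staying about
5 m from the training path on average. Rerun with
`terrain_spec("low", ...)` and `out_res = 10, gray_levels = 2` and it fails —
a featureless landscape seen through a coarse binary sensor carries too
little information, which is exactly the comparison the analytics quantify.

## Command line

A thin CLI wraps the same functions:

```sh
exec/scenefam synth --regime high --size 600 --seed 1 --out land.png --route s_curve
exec/scenefam analyze --image land.png --window 80 --res 40 --gray 10 --ridf 300,300
exec/scenefam train --image land.png --route route.csv --window 80 --res 40 --out memory.rds
exec/scenefam recap --image land.png --memory memory.rds --start 300,70 --trace trace.csv
exec/scenefam experiment --out sweep.csv
```

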