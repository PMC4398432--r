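---
title: "Navigating by scene familiarity: the model, its parameters, and its limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Navigating by scene familiarity: the model, its parameters, and its limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scenefam)
```

## The model

Insect-inspired view-based homing proposes that an animal can retrace a
learned route without a map, a coordinate system, or sequential recall: it
stores the views experienced during training and afterwards simply moves
toward whatever view is most *familiar* — most similar to something in its
store. `scenefam` implements this scheme for an aerial agent looking straight
down at a large grayscale landscape.

The primitive quantity is the **image difference score** between two equally
processed views $a$ and $b$:

$$ d(a, b) \;=\; \sum_{p \,\in\, \text{mask}} \lvert a_p - b_p \rvert , $$

the sum of absolute differences of quantized gray levels over the circular
field of view. It is symmetric, zero iff the masked cells agree, bounded by
$n_{\text{pix}}(g-1)$, and satisfies the triangle inequality. *Low difference
= high familiarity.* Two classical uses follow:

* **Attractor / catchment.** $d$ between same-heading views grows with the
  distance between their centers, so a single stored view pulls a
  gradient-descending agent back to where it was taken. The `volcano()`
  surface maps $d$ between a focal view and the views on a surrounding grid;
  `p50_summary()` condenses it into the distance at which the averaged
  cardinal slices reach half their maximum — a comparator of how much
  positional information a landscape offers.
* **Visual compass.** Rotating the current view and scoring each rotation
  against a stored view (`ridf()`, the rotational image difference function)
  recovers the stored view's bearing at the minimum of the curve.

## The sensor

`process_view()` runs a fixed pipeline at a landscape position:

1. **Crop** a `window_px` square (default 640 px; with the reference imagery
   scale of ~0.156 m/px that is a ~100 m ground patch, a 22.6° beam from
   250 m altitude — `beam_width_deg(100, 250)`).
2. **Rotate** the raw crop so that the travel bearing points "up"
   (bilinear; exact index permutation at quarter turns).
3. **Equalize** contrast per scene: a rank-based remap onto
   $255 \cdot \mathrm{cdf}(x)$. This makes the sensor invariant to any
   monotone intensity transformation of the input, emulating neural contrast
   normalization.
4. **Downsample** to `out_res` × `out_res` by block-mean pooling
   (10–80 px typical; 50 is the reference configuration).
5. **Quantize** to `gray_levels` equal-width bins (2 = black/white,
   threshold 128; 10 and 100 typical).
6. **Mask** to the inscribed circle so that rotated views compare only cells
   seen at every rotation.

Design choices a user should know about:

* **Pipeline order.** Rotation precedes equalization and pixelation; doing it
  on the raw crop minimizes interpolation artifacts. The alternative order
  (equalize after downsampling) is available via
  `sensor_config(equalize_after_downsample = TRUE)`.
* **Rotation edge handling.** Output cells whose pre-image leaves the source
  square are undefined and excluded by the mask; pre-images in the half-pixel
  rim between the pixel-center lattice and the geometric square edge clamp to
  the edge pixels, so every masked cell is always defined.
* **Mask boundary rule.** A cell belongs to the field of view iff its center
  lies strictly inside the circle of radius $n/2$ at the matrix center. For
  $n = 50$ this keeps 1,976 of 2,500 cells (79.0%); note that the analytic
  disc area $\pi \cdot 25^2 \approx 1963.5$ is slightly smaller — lattice
  counts and areas differ at this resolution, and no center-based boundary
  rule reproduces the rounded area.
* **Quantization bins** are uniform in intensity. After per-scene
  equalization, intensity bins and rank bins approximately coincide.

## Routes, memory, and the arc-scan agent

`interpolate_path()` densifies user waypoints at `spacing_px` intervals
(default 5 px ≈ one analysis-grid spacing ≈ 5 m at 1 m/px); each point carries
its segment's compass bearing (north = 0°, clockwise; a corner takes the
*outgoing* bearing — the view faced when departing the corner).
`widen_corridor()` adds one point each side, perpendicular to travel, one
spacing away: "a scene on either side" read as one scene-*spacing*, not one
window width. `build_memory()` stores the processed view of every corridor
point rotated to its bearing. Nothing else is stored: recapitulation never
reads positions or sequence out of the bank.

`recapitulate()` then iterates:

1. The first scan direction is the most familiar heading at the release
   point (`initial_heading()`, a full 360° match against the whole bank).
2. Candidate next positions lie on an arc of radius `arc_radius_m` ahead of
   the current heading, at offsets 0, +s, −s, +2s, −2s, … (default s = 10°,
   up to ±90°). Each candidate's view is rotated through 360° at
   `rotation_increment_deg` (default 10°) and scored against **all** stored
   views. The first candidate whose best score is at most
   `threshold_frac` × (mean of all rotation × memory scores at that
   candidate) is taken immediately — the early stop that makes the scan
   cheap where the route is unambiguous. If no candidate passes, the agent
   moves to the globally most familiar candidate (the unstated fallback
   case, resolved here as the argmin).
3. The next scan is cast along the **forward extension of the chosen
   chord**, not the best RIDF bearing. This gives the agent momentum: at a
   point where the route crosses itself, both branches look familiar, and
   the chord extension keeps it on its current branch (consecutive headings
   can never reverse by more than the arc half-extent).
4. Termination: within `goal_radius_m` of the training path's end
   (`reached_goal`), every arc candidate off the raster (`off_landscape`),
   or `max_steps` exhausted.

Ties break deterministically everywhere: smaller rotation angle, then
earlier memory index, then earlier arc sample. The algorithm itself has no
randomness; all stochasticity lives in landscape seeds.

**Goal radius.** The agent advances in `arc_radius_m` (20 m) jumps, so a goal
disc much smaller than a step is regularly stepped *over* even on a perfect
retrace, after which the agent overshoots and wanders. The default is
therefore one arc radius (one step length). **max_steps** defaults to
10 × route length / arc radius; the experiment harness uses 60 on its
600 m-scale fixtures, about four times what a clean retrace needs.

**Threshold reading.** "20% of the mean of difference values" is read
literally: threshold = 0.2 × mean over all rotation × memory comparisons at
the sampled point, recomputed per point. The fraction is configurable; on
terrain that mixes rich and poor regions a *stricter* fraction helps, because
the agent then exhausts the arc and takes the global best instead of the
first barely-acceptable match.

## Synthetic landscapes

`make_landscape()` emulates three information regimes so that nothing needs
downloading: **low** — near-featureless water, a faint smooth swell (σ ≈ 3
gray levels); **medium** — bright,
low-contrast sandy ground (base 205, σ ≈ 6 — deliberately a narrow intensity
band that fixed quantization bins crush unless contrast is equalized first)
dotted with darker hummocks 40–70 levels deep, one every 25–30 px so an
80 px window sees a handful (radius 4–12 px); **high** — dense
multi-scale texture: three noise octaves plus ~500 rectangular blocks per
Mpx at up to ±110 levels. All are bit-reproducible from a seed
(`withr::with_seed`), and amplitudes are chosen so the regimes order
low < medium < high on global intensity SD and, with a raw-intensity sensor,
on volcano depth and RIDF modulation.

What the generator does *not* emulate: the pixel statistics of any real
site, radiometric effects (waves, glint, shadows, seasonal change),
perspective, or sensor noise. Passing tests on these fixtures show the
algorithmic claims — information ordering, catchment scaling, the
resolution/depth failure pattern — not performance on real imagery.

One measurement subtlety: per-scene equalization normalizes every scene to
the same value distribution, so *absolute* difference sums no longer rank
regimes by information content (an equalized patch of faint swell saturates
the score scale just like a city block). Regime ordering on absolute metrics
is therefore measured with equalization off; with equalization on, regimes
are compared by catchment *shape* (p50 distance), which is scale-free.

## Numerical choices

* Bearings: `atan2(Δcol, −Δrow)` in degrees mod 360 (row grows downward;
  coordinates are 1-based `(row, col)` as usual in R).
* Crops snap to the nearest-integer top-left corner; sub-pixel placement is
  not interpolated (scene sampling is integer-spaced in practice).
* Grid margins: first/last centers inset by half a window so every window is
  croppable; within the margins centers are equally spaced.
* p50: maximum taken on the *averaged* slice curve; the first crossing from
  the center outward wins; linear interpolation between samples; an all-zero
  surface returns a `no_information` sentinel rather than an error.
* RIDF argmin ties break to the smallest angle (relevant only on degenerate,
  rotationally symmetric scenes).
* The all-pairs difference topography is O(N² · pixels); use modest grids
  (a 100 × 100 grid means 50M view pairs — run it on coarser grids first).

## Problem sizes used by the test suite

The packaged tests run everything at desk scale, as the package's own
reference conditions: 600 × 600 px landscapes at 1 m/px with 80 px windows
for the route-following checks (S-curve routes ≈ 730 m, memory banks ≈ 460
views, 20 seeds for the success-rate checks), 300–400 px fixtures for unit
and property tests, a 10° matching increment for the agent and 1° for RIDF
checks, and 6 seeds for the mixed-terrain threshold comparison. Larger
landscapes, 1° agent matching, or 100 × 100 all-pairs topographies are all
supported but are interactive-analysis material, not test material.

## Known limitations

* The agent is the deliberately simple reference algorithm: no dual
  resolution, no skyline or panoramic cues, no optimization of the scan.
* Familiarity is memorized as raw views; there is no learned network or
  capacity limit, so questions about neural storage are out of scope.
* Landscapes are static; any real-world temporal variability (lighting,
  seasons, water surface) would degrade matching in ways these fixtures
  cannot show.
* On near-featureless terrain the 20% threshold is met by aliased matches
  everywhere, and navigation degenerates to a biased random walk — visible
  in the low-regime failure tests.
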