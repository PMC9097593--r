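---
title: "Quantifying amoeboid motility and colony-front dynamics from phase-contrast time-lapse imaging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{phasetrack methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Sorocarpic amoebae such as *Fonticula alba* feed and migrate in two
morphological modes — a frequently reorienting filose form and a polarized,
directed lobose form — and invade fresh bacterial lawn as head-to-tail,
leader-led multicellular streams. Two quantitative observations anchor this
package: (i) single cells and cells in collectives move at similar
*instantaneous* speed, but collectively organized cells achieve much higher
velocities over long time intervals, and (ii) at the colony scale the
invasion front advances continually while fruiting advances in discrete
steps. Both are statements about trajectories and fronts extracted from
phase-contrast time-lapse microscopy, and both are reproduced here as
testable computations over synthetic imagery with known ground truth.

## The two preprocessing pipelines

Phase-contrast amoebae appear slightly darker than the medium and are
surrounded by a bright halo, which defeats naive thresholding. Two fixed
operator chains address this.

**Cell-shape pipeline** (for thresholded cell outlines):
intensity inversion, then local background subtraction with a circular mean
filter of kernel radius 35 px. Cells come out as bright, well-defined
shapes; Otsu's threshold and 8-connected labelling yield per-frame
components, reported as the centre of mass of the thresholded shape.
Negation commutes with any linear filter, so this composition is insensitive
to the order of its two steps; the order is nevertheless fixed and
regression-tested as part of the pipeline contract.

**Vacuole spot pipeline** (for tracking the single dark contractile vacuole
that marks each migrating cell): add 0.01 and log-transform (the offset
keeps zero-intensity pixels finite), invert by multiplication by −1,
subtract background with a rolling ball of radius 9 px, and blur with a
Gaussian of sigma 2 px. Dark vacuoles become bright, spot-like maxima. This
order is sharply non-commutative — the log must precede the inversion, and
the background subtraction must precede the blur — and is locked by tests.

The rolling ball is implemented as a grey opening by a spherical-cap
structuring element whose height profile is expressed in intensity levels
of `range(image)/255`. This reproduces the classic behaviour of the
algorithm on 8-bit data, where a radius-9 ball is shallow relative to the
signal: structures narrower than the 18 px support (the vacuole spot)
survive subtraction, broader structure (the ~20 px cell body, the
illumination field) is absorbed into the background. A cap built in raw
`[0, 1]` float units would be ~40× steeper than any feature and would eat
most of a sigma-2 peak; the scaled cap preserves such a peak to within a
few percent, which the unit tests assert. Borders are handled by
nearest-border replication throughout, avoiding spurious dark frames at
image edges.

## Detection, localization and linking

Spot candidates are local maxima within a disk of radius 7 px whose
intensity lies in the brightest 0.4% of the frame (the percentile
convention of the established particle tracker these parameters come
from), refined to the intensity-weighted centroid over the disk, iterated
to convergence (at most 10 iterations or a shift below 0.1 px), with
candidates closer than the radius merged keeping the brighter. The
discrimination score (`m0`) is computed and reported; the default cutoff of
0 disables removal. Because the intensity threshold is a *percentile* of the
whole frame, detection quality depends on the fraction of the frame covered
by objects: the synthetic scenarios keep fields of view compact (rotating
each trajectory to a canonical orientation before packing, a rigid isometry
that changes no distance) so that the threshold falls on object flanks
rather than in the noise floor — exactly the regime in which the original
protocol operates on densely populated frames.

Linking is frame-to-frame optimal assignment (a Jonker-Volkgenant style
Hungarian solver, written in-package and verified against brute-force
enumeration) minimizing total squared displacement, with per-step
displacement bounded by 10 px and gap closing over up to `linking_range - 1
= 2` missed frames; the displacement budget scales linearly with gap length
(constant-velocity assumption; a constant budget is available as an
option). Unmatched detections seed new trajectories. Merging and splitting
are deliberately out of scope: the tracked objects are vacuoles and cell
centroids, modelled as persistent points.

## Two-timescale velocity statistics

For each trajectory (positions converted to micrometres via the explicit
pixel calibration):

- *exposure-interval velocity*: displacement between consecutive points
  divided by the elapsed time (5 s per frame; gap-closed pairs use the true
  elapsed time, which is unbiased under constant velocity);
- *trajectory-time velocity*: net start-to-end displacement divided by the
  total time spanned.

The triangle inequality guarantees trajectory-time velocity never exceeds
the mean exposure-interval velocity, with equality exactly for straight
monotone motion; the suite asserts this on every simulated regime. Groups
are compared with a two-sided Mann–Whitney U test implemented from first
principles: U counts pairs with `a > b` (ties half), the p-value is exact —
from the count-distribution recursion for untied data, or complete
enumeration of rank splits for tied data when the split count is small
(≤ 2·10⁵) — whenever `n_a · n_b ≤ 400`, and otherwise uses the normal
approximation with tie and continuity corrections. The exact and
approximate paths agree to |Δp| < 0.01 at group sizes 20/20. Histograms use
left-closed, right-open bins from zero; both raw per-step pooling and
per-trajectory means are available (raw is the default — the published
panels do not state their pooling, so both are exposed).

## Colony-front dynamics

A kymograph is built by averaging each frame's intensity profile over a
band and stacking columns over time. The front position per column is the
outermost crossing, in the direction of advance, of a level set at half the
column's intensity range, interpolated linearly between straddling samples
(sub-pixel by construction, robust at moderate noise; a gradient-maximum
front would be sharper but noisier). Front speed is ordinary least squares
of position on time. Step events are found by a deliberately transparent
plateau-based greedy scheme: maximal runs with internal range below
`min_step / 2` and length at least `min_dwell` are plateaus, and
consecutive plateau pairs whose medians differ by at least `min_step` are
steps, timed at the midpoint of the inter-plateau transition. On matched
net displacement, continuous fronts give linear fits with R² > 0.99 and
zero steps while stepwise fronts give degraded fits and exactly the
injected number of steps — the computational form of "invasion is
continual, fruiting is stepwise". Penalized change-point optimization would
be a drop-in replacement but is not needed for staircase signals.

Pixel-to-centimetre and frame-to-day conversions are always explicit
calibration inputs; the package never infers macro-photography scale.

## The synthetic generator: what it emulates, and what it does not

Trajectories follow a wrapped-normal turn-angle persistent random walk with
circular standard deviation `sqrt(-2 log(persistence))`, so `persistence`
is the mean resultant length of the per-step heading change: 1 is ballistic
(lobose-like, "clear polarity"), 0 redraws the heading uniformly every step
(filose-like, "changed orientation frequently"). Chains attach followers to
their predecessors with an attraction step `follow_gain * (gap - spacing) *
dt`, capped at the gap excess so cells never close within `spacing`;
`follow_gain * dt < 1` gives smooth critically damped pursuit (the default
0.1 /s has followers adjust speed over ~10 s, filtering the sideways
swinging a rigid coupling would transmit down the chain at every leader
turn). At steady state every follower moves at the leader's speed.

Rendering adds, per cell, a soft-edged dark disk (radius 10 px at the
1 µm/px "20x" preset — a ~20 µm amoeba), a bright Gaussian halo ring, and a
dark Gaussian vacuole (sigma 2 px) at 0.6 radii behind the centre along the
cell's polarity axis; the axis is an exponentially smoothed average of step
headings (time constant 20 frames), because a cell's front–rear axis turns
over minutes rather than within one 5 s frame. Templates are evaluated
analytically at real-valued centres — no pixel snapping — so sub-pixel
localization is honestly testable. Pixel noise is i.i.d. Gaussian, clipped
to the detector range `[0, 1]`; the default preset is peak
signal-to-noise 10 for the vacuole (the reference condition for sub-pixel
localization), and detection remains reliable, without sub-pixel precision,
down to SNR 2. Fronts are rendered as a soft step profile advancing along
+x, continuously or in discrete jumps of matched net displacement.

Not emulated: real phase-contrast optics (shade-off, apodization),
cell-shape change, filose protrusions, collision/merging of collectives,
photobleaching, drift, or uneven illumination. Passing tests therefore
demonstrate correctness of the measurement chain under controlled
conditions, not robustness to every artefact of real microscopy; the
pipelines' parameters are the published protocol values, so behaviour on
real data follows the original protocol by construction.

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `dt` | 5 | s | frame interval |
| `pixel_size` | 1.0 ("20x") / 0.3 ("60x") | µm/px | explicit calibration; no published value exists, so it is always an input |
| cell `bg_radius` | 35 | px | local mean background kernel |
| spot `eps` | 0.01 | intensity | log-transform offset |
| spot `ball_radius` | 9 | px | rolling-ball radius |
| spot `blur_sigma` | 2 | px | Gaussian blur ("kernel 2" read as sigma, the convention of the software named in the protocol; configurable) |
| spot `radius` / `cutoff` / `percentile` | 7 / 0 / 0.4 | px / score / % | detection disk, discrimination cutoff, brightest-pixel percentile |
| link `linking_range` / `max_displacement` | 3 / 10 | frames / px | look-ahead (≤ 2 missed frames) and per-step displacement budget |
| metrics `min_points` | 3 | points | minimum trajectory length |
| front `min_step` / `min_dwell` | 5 / 5 | px / frames | step detector scales |

All defaults are recorded in `default_config()`; every pipeline run writes
the fully resolved configuration next to its outputs.

## Numerical choices and degenerate inputs

Otsu thresholding is used for the unspecified "thresholding" step, with a
minimum component area of 20 px² (declared, not inferred — the protocol
states none). The "local background subtraction" of the cell pipeline is a
circular mean filter; the estimator sits behind one primitive so a
rolling-ball variant can be swapped in. Constant images short-circuit to
empty detections; empty detection sets produce empty (not failing)
trajectory sets; columns of a kymograph without a level crossing are
flagged missing rather than interpolated. Assignment ties are broken
deterministically by processing detections and open tracks in (frame, y, x)
order. All randomness flows from one top-level seed through a
deterministic stream-splitting function, so identical seeds give
bit-identical stacks, CSVs and statistics.

## Problem sizes

The shipped analyses and tests use five cells over 100 frames at 5 s
(8.3 min of imaging) for the tracking benchmark, 50 trajectories per group
and 100 steps for the velocity contrast, and 60–100-frame front stacks;
these sizes give the contrast statistics p-values far below 0.01 and keep a
complete run in minutes on one core. Larger fields behave identically
except for the percentile-threshold coverage effect described above.

## Known limitations

- The spot detector's percentile threshold couples detection to frame
  coverage; nearly empty fields of view require raising `percentile`.
- The linker is greedy per frame pair (Hungarian per frame, then gap
  closing), not a global spatiotemporal optimization; in the well-separated
  regime of these data the two coincide (the suite verifies optimality per
  frame pair by exhaustive enumeration), but dense crossings could differ.
- Exact Mann–Whitney p-values with ties fall back to the normal
  approximation when the split count exceeds 2·10⁵.
- Absolute µm/s axes of the published velocity figures are not reproducible
  because no pixel calibration is published; all velocity recovery is
  validated against injected synthetic truth instead.
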