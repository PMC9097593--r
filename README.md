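# phasetrack

Quantitative motility analysis for phase-contrast time-lapse microscopy of
amoeboid cells, built around the collective-invasion behaviour of sorocarpic
amoebae (*Fonticula alba*): cells invade fresh bacterial lawn as
head-to-tail, leader-led streams, move with a single dark contractile
vacuole at their rear, and advance the colony front continually while
fruiting sweeps across the colony in discrete steps.

The package is aimed at microscopists and image analysts who want the full
measurement chain — preprocessing, detection, linking, statistics — as
tested, scriptable R functions rather than an interactive tool.

## What it computes

**Preprocessing.** Two fixed operator chains: the cell-shape pipeline
(invert, local background subtraction with kernel radius 35 px) and the
vacuole spot pipeline (add 0.01, log, invert by −1, rolling-ball background
subtraction radius 9 px, Gaussian blur sigma 2 px).

**Detection and linking.** Otsu-thresholded shape centres of mass for cell
outlines; sub-pixel spot detection (radius 7, cutoff 0, percentile 0.4) for
vacuoles; optimal-assignment linking with displacement bound 10 px and gap
closing over a linking range of 3 frames.

**Two-timescale velocities.** For a trajectory with positions *r(t)*:

- exposure-interval velocity: |r(t+Δt) − r(t)| / Δt, Δt = 5 s;
- trajectory-time velocity: |r(T) − r(0)| / T.

Directed and random movers match on the first and separate several-fold on
the second; groups are compared with an exact two-sided Mann–Whitney U test
(U = #{a<sub>i</sub> > b<sub>j</sub>} + ½#{a<sub>i</sub> = b<sub>j</sub>},
exact p by enumeration for n<sub>a</sub>·n<sub>b</sub> ≤ 400, normal
approximation with tie and continuity corrections above).

**Front dynamics.** Kymographs, sub-pixel front extraction by level-set
crossing, least-squares front speed, and plateau-based step detection —
continuous fronts fit linearly (R² > 0.99, zero steps), stepwise fronts
yield exactly their injected step count.

**Synthetic ground truth.** A persistent-random-walk / leader-follower
simulator and a phase-contrast renderer (dark soft-edged body, bright halo,
dark rear vacuole, Gaussian noise) provide end-to-end benchmarks with known
truth; no real raw imagery is required anywhere.

## Worked example

```r
library(phasetrack)

# five directed cells, 100 frames at 5 s, rendered with ground truth
sim <- simulate_spot_benchmark(n_cells = 5, n_frames = 100, dt = 5, seed = 1)
res <- run_spot_pipeline(sim$stack, default_config())

ev <- evaluate_detections(res$detections, sim$truth, kind = "vacuole")
c(precision = ev$precision, recall = ev$recall, bias_px = ev$bias)
#> precision    recall   bias_px
#>  1.000000  1.000000  0.142...
mean(res$metrics$mean_frame_velocity)   # injected speed was 0.25 um/s
#> [1] 0.2436...

# matched-speed directed chains vs random movers
grp <- simulate_contrast_groups(n_per_group = 50, n_steps = 100, seed = 1)
compare_motility(grp$chain, grp$random, "trajectory_time")
#> Mann-Whitney U comparison (normal approximation)
#>   group a: mean = 0.1686 (n = 50)
#>   group b: mean = 0.01763 (n = 50)
#>   U = 2499, two-sided p = 7.5e-18
```

The first block shows the tracker recovering every rendered vacuole
(precision and recall 1 at a 3 px match radius) with a mean localization
bias of ~0.14 px, and the injected 0.25 µm/s speed recovered to within ~3%.
The second shows the two-timescale contrast: both groups move at ~0.2 µm/s
per 5 s interval, but over the full trajectory the directed group is ~10×
faster, with U at its maximum (2499 of 2500) — the statistical signature of
directed collective migration.

The numbered scripts under `analysis/` run the complete study: simulate the
scenarios, track cells and vacuoles, compute the velocity statistics, and
classify continuous vs stepwise fronts, writing tables under `results/`.

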