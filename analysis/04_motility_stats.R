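#!/usr/bin/env Rscript
# Two-timescale velocity statistics: directed leader-follower chains versus
# persistence-0 random movers at matched speed. On the 5 s exposure
# interval the groups are nearly indistinguishable; over the trajectory
# time the directed group is an order of magnitude faster — the
# computational signature of collective directed migration.

suppressMessages(library(phasetrack))

grp <- simulate_contrast_groups(n_per_group = 50, n_steps = 100, seed = 1)
dir.create("results/motility", recursive = TRUE, showWarnings = FALSE)

for (ts in c("exposure_interval", "trajectory_time")) {
  g <- compare_motility(grp$chain, grp$random, ts)
  message(sprintf("%s: chain %.4f vs random %.4f um/s (ratio %.2f), U = %g, p = %.3g",
                  ts, g$mean_a, g$mean_b, g$mean_a / g$mean_b, g$U, g$p))
  write_group_comparison(g, file.path("results/motility",
                                      paste0("comparison_", ts, ".json")))
}

# velocity histograms (0.05 um/s bins), one CSV per group and timescale
for (nm in c("chain", "random")) {
  tr <- grp[[nm]]
  fv <- frame_velocities(tr)$value
  tv <- trajectory_velocity(tr)$value
  for (set in list(c("exposure", "fv"), c("trajectory", "tv"))) {
    v <- if (set[2] == "fv") fv else tv
    h <- velocity_histogram(v, bin_width = 0.05)
    write_table_csv(data.frame(bin_left = head(h$edges, -1),
                               bin_right = tail(h$edges, -1),
                               count = h$counts),
                    sprintf("results/motility/hist_%s_%s.csv", nm, set[1]))
  }
}
message("histograms written under results/motility/")
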