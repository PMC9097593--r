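# Two-timescale velocity statistics and Mann-Whitney comparison.

make_traj <- function(x, y, dt = 5, id = 1L) {
  n <- length(x)
  out <- data.frame(traj_id = id, frame = 0:(n - 1), t = (0:(n - 1)) * dt,
                    x = x, y = y)
  attr(out, "unit") <- "um"
  out
}

test_that("frame velocities match hand-computed displacements", {
  # straight mover: 1 um per 5 s frame
  tr <- make_traj(seq(0, 10, by = 1), rep(0, 11))
  fv <- frame_velocities(tr)
  expect_equal(fv$value, rep(0.2, 10))
  # stationary
  expect_equal(frame_velocities(make_traj(rep(1, 5), rep(2, 5)))$value, rep(0, 4))
  # 3-4-5 triangle over one 5 s interval
  fv <- frame_velocities(make_traj(c(0, 3), c(0, 4)))
  expect_equal(fv$value, 1.0)
  expect_error(frame_velocities(make_traj(1, 1)), ">= 2 points")
})

test_that("gap-closed steps use true elapsed time", {
  tr <- data.frame(traj_id = 1L, frame = c(0, 1, 3), t = c(0, 5, 15),
                   x = c(0, 1, 3), y = 0)
  attr(tr, "unit") <- "um"
  fv <- frame_velocities(tr)
  expect_equal(fv$value, c(0.2, 0.2))
})

test_that("trajectory-time velocity is net displacement over elapsed time", {
  tr <- make_traj(seq(0, 10, by = 1), rep(0, 11))
  expect_equal(trajectory_velocity(tr)$value, 0.2)
  # closed loop returns to start
  loop <- make_traj(c(0, 1, 1, 0, 0), c(0, 0, 1, 1, 0))
  expect_equal(trajectory_velocity(loop)$value, 0)
})

test_that("random-walk trajectory velocity decays as 1/sqrt(n)", {
  n <- 100; speed <- 1
  vals <- vapply(1:1000, function(i) {
    tr <- simulate_prw(motion_params(speed = speed, persistence = 0, dt = 1,
                                     n_steps = n, seed = 5000 + i))
    trajectory_velocity(tr)$value
  }, 0)
  # E[net]/t = s * sqrt(pi / (4 n)); at n = 100 that is ~0.089 s
  expect_lt(mean(vals) / speed, 0.25)
  expect_equal(mean(vals) / speed, sqrt(pi / (4 * n)), tolerance = 0.1)
})

test_that("mean velocity is the arithmetic mean and order-invariant", {
  expect_equal(mean_velocity(c(0.1, 0.3)), 0.2)
  expect_equal(mean_velocity(0.7), 0.7)
  expect_equal(mean_velocity(c(3, 1, 2)), mean_velocity(c(2, 3, 1)))
  expect_error(mean_velocity(numeric(0)), "no samples")
})

test_that("Mann-Whitney U matches enumeration on the canonical examples", {
  g <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(g$U, 0)
  expect_equal(g$p, 1 / 3, tolerance = 1e-12)
  g <- mann_whitney_u(5, c(1, 2, 3))
  expect_equal(g$U, 3)
  expect_equal(g$p, 0.5, tolerance = 1e-12)
  # identical multisets: U = n^2 / 2
  g <- mann_whitney_u(c(1, 2, 3), c(1, 2, 3))
  expect_equal(g$U, 4.5)
})

test_that("exact U path agrees with stats::wilcox.test on untied samples", {
  set.seed(13)
  for (i in 1:10) {
    a <- rnorm(sample(3:12, 1)); b <- rnorm(sample(3:12, 1))
    g <- mann_whitney_u(a, b)
    w <- wilcox.test(a, b, exact = TRUE)
    expect_equal(g$U, unname(w$statistic))
    expect_equal(g$p, w$p.value, tolerance = 1e-10)
  }
})

test_that("exact and normal-approximation p agree within 0.01 at n = 20/20", {
  set.seed(14)
  for (i in 1:10) {
    a <- rnorm(20); b <- rnorm(20, mean = runif(1, -1, 1))
    pe <- mann_whitney_u(a, b)$p
    pn <- mann_whitney_u(a, b, exact_limit = 0)$p
    expect_lt(abs(pe - pn), 0.01)
  }
})

test_that("tied samples are handled by enumeration", {
  a <- c(1, 2, 2); b <- c(2, 3)
  g <- mann_whitney_u(a, b)
  expect_equal(g$U, sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "==")))
  ref <- brute_mwu(a, b)
  expect_equal(g$p, ref$p, tolerance = 1e-12)
})

test_that("group comparison invariants hold", {
  set.seed(15)
  a <- runif(8); b <- runif(12)
  g <- mann_whitney_u(a, b)
  expect_gte(g$U, 0); expect_lte(g$U, g$n_a * g$n_b)
  expect_gte(g$p, 0); expect_lte(g$p, 1)
  expect_error(mann_whitney_u(numeric(0), b), "non-empty")
})

test_that("compare_motility separates directed chains from random movers", {
  sim <- simulate_contrast_groups(n_per_group = 20, n_steps = 80, seed = 3)
  gt <- compare_motility(sim$chain, sim$random, "trajectory_time")
  expect_gt(gt$mean_a / gt$mean_b, 3)
  expect_lt(gt$p, 0.01)
  ge <- compare_motility(sim$chain, sim$random, "exposure_interval")
  expect_lt(abs(ge$mean_a / ge$mean_b - 1), 0.1)
})

test_that("a group compared with itself is not significant", {
  sim <- simulate_contrast_groups(n_per_group = 15, n_steps = 50, seed = 4)
  g <- compare_motility(sim$random, sim$random, "trajectory_time")
  expect_gt(g$p, 0.9)
})

test_that("trajectory velocity never exceeds mean frame velocity (triangle inequality)", {
  regimes <- list(
    simulate_prw(motion_params(0.2, 0, dt = 5, n_steps = 60, seed = 21)),
    simulate_prw(motion_params(0.2, 0.7, dt = 5, n_steps = 60, seed = 22)),
    simulate_prw(motion_params(0.2, 1, dt = 5, n_steps = 60, seed = 23)),
    simulate_chain(chain_params(3, motion_params(0.2, 0.9, dt = 5, n_steps = 60,
                                                 seed = 24))))
  for (tr in regimes) {
    tv <- trajectory_velocity(tr)
    fv <- frame_velocities(tr)
    for (id in unique(tr$traj_id)) {
      expect_lte(tv$value[tv$traj_id == id],
                 mean(fv$value[fv$traj_id == id]) + 1e-12)
    }
  }
  # equality holds exactly for straight monotone motion
  straight <- simulate_prw(motion_params(0.2, 1, dt = 5, n_steps = 30, seed = 25))
  expect_equal(trajectory_velocity(straight)$value,
               mean(frame_velocities(straight)$value), tolerance = 1e-12)
})

test_that("velocity histograms use half-open bins from zero", {
  h <- velocity_histogram(c(0.05, 0.15), 0.1)
  expect_equal(h$counts, c(1, 1))
  expect_equal(h$edges, c(0, 0.1, 0.2))
  # boundary value falls in the upper bin
  h <- velocity_histogram(c(0.1), 0.1)
  expect_equal(h$counts, c(0, 1))
  h <- velocity_histogram(numeric(0), 0.1)
  expect_equal(sum(h$counts), 0)
  h <- velocity_histogram(runif(50), 0.13)
  expect_equal(sum(h$counts), 50)
})
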