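# Persistent random walk and leader-follower chain generators.

test_that("prw with full persistence is a straight line at the set speed", {
  mp <- motion_params(speed = 0.1, persistence = 1, dt = 5, n_steps = 10, seed = 1)
  tr <- simulate_prw(mp)
  expect_equal(nrow(tr), 11)
  net <- sqrt((tr$x[11] - tr$x[1])^2 + (tr$y[11] - tr$y[1])^2)
  expect_equal(net, 5.0, tolerance = 1e-12)
  # every step has length speed * dt
  steps <- sqrt(diff(tr$x)^2 + diff(tr$y)^2)
  expect_equal(steps, rep(0.5, 10), tolerance = 1e-12)
})

test_that("zero speed keeps all positions identical", {
  tr <- simulate_prw(motion_params(speed = 0, persistence = 0.5, dt = 1,
                                   n_steps = 20, seed = 2))
  expect_equal(diff(range(tr$x)), 0)
  expect_equal(diff(range(tr$y)), 0)
})

test_that("identical seed and parameters reproduce identical trajectories", {
  mp <- motion_params(speed = 0.2, persistence = 0.6, dt = 5, n_steps = 50, seed = 99)
  expect_identical(simulate_prw(mp), simulate_prw(mp))
})

test_that("invalid motion parameters are rejected with clear messages", {
  expect_error(motion_params(speed = -1, persistence = 0.5), "non-negative")
  expect_error(motion_params(speed = 1, persistence = 0.5, dt = 0), "positive")
  expect_error(motion_params(speed = 1, persistence = 2), "persistence")
  expect_error(motion_params(speed = 1, persistence = 0.5, n_steps = 0), "n_steps")
})

test_that("persistence-0 walks follow diffusive scaling, persistence-1 ballistic", {
  # Monte-Carlo estimate of the growth exponent of mean net displacement
  # with step count: fit log E|r(n)| ~ log n over checkpoints.
  checkpoints <- c(100, 300, 1000, 3000, 10000)
  n_rep <- 200
  mean_disp <- vapply(checkpoints, function(cp) 0, 0)
  disp <- matrix(0, n_rep, length(checkpoints))
  for (i in seq_len(n_rep)) {
    tr <- simulate_prw(motion_params(speed = 1, persistence = 0, dt = 1,
                                     n_steps = max(checkpoints), seed = 1000 + i))
    disp[i, ] <- sqrt(tr$x[checkpoints + 1]^2 + tr$y[checkpoints + 1]^2)
  }
  fit <- lm(log(colMeans(disp)) ~ log(checkpoints))
  expect_lt(abs(coef(fit)[2] - 0.5), 0.05)
  # ballistic: displacement exactly linear in n
  tr <- simulate_prw(motion_params(speed = 1, persistence = 1, dt = 1,
                                   n_steps = 1000, seed = 5))
  expect_equal(sqrt(tr$x[1001]^2 + tr$y[1001]^2), 1000, tolerance = 1e-9)
})

test_that("followers of a straight leader reach leader speed along its path", {
  cp <- chain_params(n_cells = 4,
                     leader = motion_params(speed = 0.2, persistence = 1, dt = 5,
                                            n_steps = 60, seed = 3),
                     spacing = 5, follow_gain = 0.1)
  tr <- simulate_chain(cp)
  expect_equal(length(unique(tr$traj_id)), 4)
  # after a transient, each follower moves at the leader step length
  for (id in 2:4) {
    s <- tr[tr$traj_id == id, ]
    steps <- sqrt(diff(s$x)^2 + diff(s$y)^2)
    expect_equal(mean(tail(steps, 20)), 0.2 * 5, tolerance = 1e-6)
  }
})

test_that("followers with zero gain never move", {
  cp <- chain_params(n_cells = 3,
                     leader = motion_params(speed = 0.2, persistence = 0.8, dt = 5,
                                            n_steps = 30, seed = 4),
                     spacing = 5, follow_gain = 0)
  tr <- simulate_chain(cp)
  for (id in 2:3) {
    s <- tr[tr$traj_id == id, ]
    expect_equal(diff(range(s$x)), 0)
    expect_equal(diff(range(s$y)), 0)
  }
})

test_that("chain followers match leader trajectory-time velocity within 10%", {
  # net displacements compared over replicate chains: each follower's
  # start/end offsets within the chain enter a single run with random sign,
  # so the ratio is a Monte-Carlo average
  tvs <- lapply(1:10, function(i) {
    cp <- chain_params(n_cells = 5,
                       leader = motion_params(speed = 0.2, persistence = 0.9,
                                              dt = 5, n_steps = 500,
                                              seed = 700 + i),
                       spacing = 5, follow_gain = 0.1)
    trajectory_velocity(simulate_chain(cp))
  })
  leader_mean <- mean(vapply(tvs, function(tv) tv$value[tv$traj_id == 1], 0))
  for (id in 2:5) {
    fol <- mean(vapply(tvs, function(tv) tv$value[tv$traj_id == id], 0))
    expect_lt(abs(fol / leader_mean - 1), 0.10)
  }
})

test_that("head-to-tail gaps never go negative", {
  cp <- chain_params(n_cells = 3,
                     leader = motion_params(speed = 0.3, persistence = 0.3, dt = 5,
                                            n_steps = 100, seed = 12),
                     spacing = 4, follow_gain = 2)
  tr <- simulate_chain(cp)
  wide <- split(tr, tr$traj_id)
  for (k in 2:3) {
    gaps <- sqrt((wide[[k - 1]]$x - wide[[k]]$x)^2 +
                 (wide[[k - 1]]$y - wide[[k]]$y)^2)
    expect_true(all(gaps >= -1e-9))
  }
})
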