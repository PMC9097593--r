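#' Motion parameters for a persistent random walk
#'
#' The motion model is a wrapped-normal turn-angle persistent random walk:
#' each step has length `speed * dt` and the heading changes between steps by
#' a wrapped-normal angle with circular standard deviation
#' `sigma_theta = sqrt(-2 * log(persistence))`, so that `persistence` is the
#' mean resultant length of the per-step heading change. `persistence = 1`
#' gives straight (ballistic) motion; `persistence = 0` draws each step
#' heading independently and uniformly on `[0, 2*pi)`. This one-parameter
#' family spans the directed (lobose, collective) and frequently reorienting
#' (filose) regimes of amoeboid motility.
#'
#' @param speed cell speed, micrometres per second (>= 0).
#' @param persistence directional correlation per step, in `[0, 1]`.
#' @param dt time step, seconds (> 0).
#' @param n_steps number of steps (>= 1); trajectories have `n_steps + 1` points.
#' @param seed integer seed, or `NULL` to use the current RNG state.
#' @return an object of class `motion_params`.
#' @export
motion_params <- function(speed, persistence, dt = 5, n_steps = 100, seed = NULL) {
  if (!is.numeric(speed) || length(speed) != 1 || is.na(speed) || speed < 0)
    stop("speed must be a single non-negative number (um/s)")
  if (!is.numeric(persistence) || persistence < 0 || persistence > 1)
    stop("persistence must lie in [0, 1]")
  if (!is.numeric(dt) || dt <= 0) stop("dt must be a positive time step (s)")
  if (!is.numeric(n_steps) || n_steps < 1) stop("n_steps must be >= 1")
  structure(list(speed = speed, persistence = persistence, dt = dt,
                 n_steps = as.integer(n_steps), seed = seed),
            class = "motion_params")
}

# Build the canonical trajectory data.frame.
trajectory_df <- function(traj_id, frame, t, x, y, unit = "um") {
  out <- data.frame(traj_id = traj_id, frame = as.integer(frame),
                    t = t, x = x, y = y)
  attr(out, "unit") <- unit
  out
}

#' Unit (px or um) of a trajectory table
#' @param traj a trajectory data.frame.
#' @export
traj_unit <- function(traj) {
  u <- attr(traj, "unit")
  if (is.null(u)) "um" else u
}

#' Convert pixel-unit trajectories to micrometres
#' @param traj a trajectory data.frame in pixel units.
#' @param pixel_size micrometres per pixel.
#' @export
convert_trajectories <- function(traj, pixel_size) {
  if (traj_unit(traj) == "um") return(traj)
  traj$x <- traj$x * pixel_size
  traj$y <- traj$y * pixel_size
  attr(traj, "unit") <- "um"
  traj
}

#' Simulate a persistent random walk trajectory
#'
#' @param params a [motion_params()] object.
#' @param start numeric length-2 start position (um).
#' @param heading0 initial heading in radians, or `NULL` to draw uniformly.
#' @param traj_id identifier for the output trajectory.
#' @return a trajectory data.frame with columns `traj_id`, `frame` (0-based),
#'   `t` (s), `x`, `y` (um); `n_steps + 1` rows.
#' @export
simulate_prw <- function(params, start = c(0, 0), heading0 = NULL, traj_id = 1L) {
  stopifnot(inherits(params, "motion_params"))
  n <- params$n_steps
  with_seed(params$seed, {
    h0 <- if (is.null(heading0)) runif(1, 0, 2 * pi) else heading0
    if (params$persistence >= 1) {
      headings <- rep(h0, n)
    } else if (params$persistence <= 0) {
      headings <- runif(n, 0, 2 * pi)
      headings[1] <- h0
    } else {
      sigma <- sqrt(-2 * log(params$persistence))
      turns <- rnorm(n - 1, 0, sigma)
      headings <- h0 + cumsum(c(0, turns))
    }
    step <- params$speed * params$dt
    x <- start[1] + cumsum(c(0, step * cos(headings)))
    y <- start[2] + cumsum(c(0, step * sin(headings)))
    trajectory_df(traj_id, 0:n, (0:n) * params$dt, x, y)
  })
}

#' Parameters for a leader-follower chain
#'
#' Emulates head-to-tail multicellular streams: a leader cell performs a
#' persistent random walk and each follower is attracted to its predecessor.
#' At every step, follower `k` moves toward the current position of cell
#' `k - 1` by `follow_gain * (gap - spacing) * dt`, capped at the gap
#' excess so the head-to-tail gap never drops below `spacing` (and hence
#' never below 0). With `follow_gain = 0` followers never move; otherwise
#' the chain settles at an equilibrium gap between `spacing` and
#' `spacing + speed / follow_gain` where every follower moves at the
#' leader's speed along the leader's path, briefly speeding up to catch up
#' again after the leader turns.
#'
#' `follow_gain * dt` below 1 gives smooth, critically damped pursuit; the
#' default (0.1 /s at the 5 s frame interval) has followers adjust their
#' speed over ~10 s, which filters out the sideways swinging a stiffer
#' coupling would transmit down the chain every time the leader turns.
#'
#' @param n_cells number of cells in the chain (>= 2), leader included.
#' @param leader a [motion_params()] object for the leader.
#' @param spacing target head-to-tail gap, micrometres (> 0).
#' @param follow_gain follower attraction strength, 1/s (>= 0).
#' @export
chain_params <- function(n_cells, leader, spacing = 5, follow_gain = 0.1) {
  if (!is.numeric(n_cells) || n_cells < 2) stop("n_cells must be >= 2")
  stopifnot(inherits(leader, "motion_params"))
  if (!is.numeric(spacing) || spacing <= 0) stop("spacing must be > 0 (um)")
  if (!is.numeric(follow_gain) || follow_gain < 0) stop("follow_gain must be >= 0 (1/s)")
  structure(list(n_cells = as.integer(n_cells), leader = leader,
                 spacing = spacing, follow_gain = follow_gain),
            class = "chain_params")
}

#' Simulate a leader-follower chain
#'
#' @param params a [chain_params()] object.
#' @return a trajectory data.frame with `traj_id` 1 (leader) to `n_cells`,
#'   all sharing the same frame times.
#' @export
simulate_chain <- function(params) {
  stopifnot(inherits(params, "chain_params"))
  lp <- params$leader
  leader <- simulate_prw(lp, traj_id = 1L)
  n <- lp$n_steps
  k <- params$n_cells
  # Initial placement: followers behind the leader's initial heading at the
  # equilibrium gap, so the chain starts in (or near) steady state.
  d1 <- c(leader$x[2] - leader$x[1], leader$y[2] - leader$y[1])
  if (sqrt(sum(d1^2)) < 1e-12) d1 <- c(1, 0)
  u0 <- d1 / sqrt(sum(d1^2))
  gap0 <- if (params$follow_gain > 0)
    params$spacing + lp$speed / params$follow_gain else params$spacing
  pos <- matrix(0, nrow = k, ncol = 2)
  pos[1, ] <- c(leader$x[1], leader$y[1])
  for (j in 2:k) pos[j, ] <- pos[1, ] - u0 * gap0 * (j - 1)

  X <- matrix(0, nrow = n + 1, ncol = k)
  Y <- matrix(0, nrow = n + 1, ncol = k)
  X[1, ] <- pos[, 1]; Y[1, ] <- pos[, 2]
  for (ti in seq_len(n)) {
    pos[1, ] <- c(leader$x[ti + 1], leader$y[ti + 1])
    for (j in 2:k) {
      v <- pos[j - 1, ] - pos[j, ]
      dist <- sqrt(sum(v^2))
      if (dist > 1e-12) {
        want <- params$follow_gain * (dist - params$spacing) * lp$dt
        len <- min(max(0, want), max(0, dist - params$spacing))
        pos[j, ] <- pos[j, ] + v / dist * len
      }
    }
    X[ti + 1, ] <- pos[, 1]; Y[ti + 1, ] <- pos[, 2]
  }
  out <- do.call(rbind, lapply(seq_len(k), function(j) {
    trajectory_df(j, 0:n, (0:n) * lp$dt, X[, j], Y[, j])
  }))
  attr(out, "unit") <- "um"
  out
}
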