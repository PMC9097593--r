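# Preset simulation scenarios: the study conditions exercised by the
# analysis scripts, the test suite and the acceptance script.

# Pack independent pixel-unit trajectories into non-overlapping horizontal
# lanes: each trajectory is rotated about its centroid so its principal
# axis is horizontal (a rigid isometry — distances, and hence speeds, are
# unchanged), then translated into its own lane with a separation margin.
# Rotation keeps the frame compact for directed movers, which keeps the
# percentile-based spot detector's intensity threshold on the objects
# rather than in the noise floor.
pack_trajectories <- function(trajs, margin = 18, sep = 25, rotate = TRUE) {
  ids <- unique(trajs$traj_id)
  rotated <- lapply(ids, function(id) {
    s <- trajs[trajs$traj_id == id, ]
    s <- s[order(s$frame), ]
    if (rotate && nrow(s) > 1) {
      cx <- mean(s$x); cy <- mean(s$y)
      xc <- s$x - cx; yc <- s$y - cy
      theta <- 0.5 * atan2(2 * sum(xc * yc), sum(xc^2) - sum(yc^2))
      co <- cos(-theta); si <- sin(-theta)
      s$x <- cx + co * xc - si * yc
      s$y <- cy + si * xc + co * yc
    }
    s
  })
  y0 <- margin
  out <- do.call(rbind, lapply(rotated, function(s) {
    s$x <- s$x - min(s$x) + margin
    h <- diff(range(s$y))
    s$y <- s$y - min(s$y) + y0
    y0 <<- y0 + h + sep
    s
  }))
  attr(out, "unit") <- "px"
  rownames(out) <- NULL
  out
}

#' Simulate the vacuole-tracking benchmark stack
#'
#' Independent persistently migrating lobose-like cells rendered at the low
#' magnification used for vacuole tracking (1 um/px), with ground truth.
#' Cells are laid out in separated lanes so that detection and identity
#' assignment are unambiguous, emulating a field of view with
#' well-separated directed migrating amoebae.
#'
#' @param n_cells number of cells (default 5).
#' @param n_frames frames (default 100; `n_frames - 1` steps).
#' @param speed true cell speed, um/s.
#' @param persistence directional persistence of each cell (default 0.99,
#'   strongly polarized directed migration).
#' @param dt frame interval, s.
#' @param rp [render_params()]; its `pixel_size` calibrates the stack.
#' @param seed top-level seed.
#' @return list with `stack`, `truth`, `trajs_px` (ground-truth pixel
#'   trajectories) and `speed` (the injected truth, um/s).
#' @export
simulate_spot_benchmark <- function(n_cells = 5, n_frames = 100, speed = 0.25,
                                    persistence = 0.99, dt = 5,
                                    rp = render_params(pixel_size = 1),
                                    seed = 1) {
  trajs <- do.call(rbind, lapply(seq_len(n_cells), function(i) {
    mp <- motion_params(speed = speed, persistence = persistence, dt = dt,
                        n_steps = n_frames - 1, seed = derive_seed(seed, i))
    simulate_prw(mp, traj_id = i)
  }))
  # to px and packed into non-overlapping regions
  trajs_px <- trajs
  trajs_px$x <- trajs$x / rp$pixel_size
  trajs_px$y <- trajs$y / rp$pixel_size
  attr(trajs_px, "unit") <- "px"
  trajs_px <- pack_trajectories(trajs_px, margin = 3 * rp$cell_radius)
  rp$seed <- derive_seed(seed, 0, 1)
  r <- render_stack(trajs_px, rp, dt = dt)
  list(stack = r$stack, truth = r$truth, trajs_px = trajs_px, speed = speed)
}

#' Simulate matched-speed directed-chain and random trajectory groups
#'
#' The computational form of the two-timescale contrast: leader-led chains
#' (directed migration) versus independent persistence-0 random movers at
#' the same speed. On the exposure-interval timescale the groups are
#' indistinguishable; on the trajectory timescale the directed group is
#' several-fold faster.
#'
#' @param n_per_group trajectories per group (default 50).
#' @param n_steps steps per trajectory (default 100).
#' @param speed common speed, um/s.
#' @param dt frame interval, s.
#' @param chain_size cells per chain (default 5; `n_per_group` must be a
#'   multiple).
#' @param leader_persistence persistence of chain leaders (default 0.99: the
#'   near-straight outward paths of invasion streams).
#' @param seed top-level seed.
#' @return list with `chain` and `random` trajectory data.frames (um).
#' @export
simulate_contrast_groups <- function(n_per_group = 50, n_steps = 100,
                                     speed = 0.2, dt = 5, chain_size = 5,
                                     leader_persistence = 0.99, seed = 1) {
  stopifnot(n_per_group %% chain_size == 0)
  n_chains <- n_per_group / chain_size
  chain <- do.call(rbind, lapply(seq_len(n_chains), function(i) {
    cp <- chain_params(
      n_cells = chain_size,
      leader = motion_params(speed = speed, persistence = leader_persistence,
                             dt = dt, n_steps = n_steps,
                             seed = derive_seed(seed, i, 1)),
      spacing = 5, follow_gain = 0.1)
    tr <- simulate_chain(cp)
    tr$traj_id <- tr$traj_id + (i - 1) * chain_size
    tr
  }))
  attr(chain, "unit") <- "um"
  random <- do.call(rbind, lapply(seq_len(n_per_group), function(i) {
    mp <- motion_params(speed = speed, persistence = 0, dt = dt,
                        n_steps = n_steps, seed = derive_seed(seed, i, 2))
    simulate_prw(mp, traj_id = i)
  }))
  attr(random, "unit") <- "um"
  list(chain = chain, random = random)
}
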