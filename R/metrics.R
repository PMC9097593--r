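# Two-timescale velocity statistics and nonparametric group comparison.
#
# Two velocities are distinguished. The exposure-interval velocity is the
# displacement between consecutive points divided by the elapsed time (the
# frame interval, or the true elapsed time across a closed gap) — it
# measures instantaneous speed and is blind to directionality. The
# trajectory-time velocity is the net start-to-end displacement divided by
# the total time spanned by the trajectory — it is high only for directed
# motion. Directed collectives and random movers can match on the first
# timescale yet differ several-fold on the second.

split_trajs <- function(traj) split(traj, traj$traj_id)

#' Exposure-interval (frame-to-frame) velocities
#'
#' For each consecutive point pair of each trajectory: Euclidean
#' displacement divided by the elapsed time. Pairs spanning a closed gap use
#' the actual elapsed time, not the nominal frame interval.
#'
#' @param traj a trajectory data.frame (positions in um, `t` in s, for
#'   velocities in um/s).
#' @return a data.frame with `traj_id`, `value`, `timescale`.
#' @export
frame_velocities <- function(traj) {
  parts <- split_trajs(traj)
  bad <- names(parts)[vapply(parts, nrow, 0L) < 2]
  if (length(bad))
    stop("frame_velocities needs >= 2 points per trajectory (violated by: ",
         paste(bad, collapse = ", "), ")")
  out <- do.call(rbind, lapply(parts, function(s) {
    s <- s[order(s$frame), ]
    d <- sqrt(diff(s$x)^2 + diff(s$y)^2)
    dt <- diff(s$t)
    data.frame(traj_id = s$traj_id[-1], value = d / dt,
               timescale = "exposure_interval")
  }))
  rownames(out) <- NULL
  out
}

#' Trajectory-time velocity
#'
#' Net Euclidean displacement between the first and last positions divided
#' by the total time spanned, one value per trajectory.
#'
#' @inheritParams frame_velocities
#' @return a data.frame with `traj_id`, `value`, `timescale`.
#' @export
trajectory_velocity <- function(traj) {
  parts <- split_trajs(traj)
  bad <- names(parts)[vapply(parts, nrow, 0L) < 2]
  if (length(bad))
    stop("trajectory_velocity needs >= 2 points per trajectory (violated by: ",
         paste(bad, collapse = ", "), ")")
  out <- do.call(rbind, lapply(parts, function(s) {
    s <- s[order(s$frame), ]
    n <- nrow(s)
    elapsed <- s$t[n] - s$t[1]
    if (elapsed <= 0) stop("trajectory ", s$traj_id[1], " spans zero time")
    data.frame(traj_id = s$traj_id[1],
               value = sqrt((s$x[n] - s$x[1])^2 + (s$y[n] - s$y[1])^2) / elapsed,
               timescale = "trajectory_time")
  }))
  rownames(out) <- NULL
  out
}

#' Arithmetic mean of velocity samples
#' @param samples a numeric vector or a data.frame with a `value` column.
#' @export
mean_velocity <- function(samples) {
  v <- if (is.data.frame(samples)) samples$value else samples
  if (!length(v)) stop("mean_velocity: no samples")
  mean(v)
}

# Exact null distribution of U (no ties): counts of rank splits per U value,
# via the recurrence c(n1, n2, u) = c(n1-1, n2, u - n2) + c(n1, n2-1, u).
u_count_distribution <- function(na, nb) {
  maxu <- na * nb
  zero <- c(1, rep(0, maxu))
  # col[[n1+1]] = counts over u = 0..maxu at the current n2
  col <- rep(list(zero), na + 1)                 # n2 = 0: only U = 0
  for (n2 in seq_len(nb)) {
    newcol <- vector("list", na + 1)
    newcol[[1]] <- zero                          # n1 = 0: only U = 0
    for (n1 in seq_len(na)) {
      prev_n1 <- newcol[[n1]]                    # c(n1-1, n2, u - n2)
      shifted <- if (n2 > maxu) rep(0, maxu + 1) else
        c(rep(0, n2), head(prev_n1, maxu + 1 - n2))
      newcol[[n1 + 1]] <- shifted + col[[n1 + 1]]
    }
    col <- newcol
  }
  col[[na + 1]]
}

#' Mann-Whitney U test
#'
#' `U` is reported for group `a`: the number of pairs with `a_i > b_j`, ties
#' counted one half. The two-sided p-value is exact — computed from the full
#' null distribution of rank splits — when `n_a * n_b <= exact_limit`
#' (count-distribution recursion without ties; complete enumeration of
#' splits for tied data when feasible), and otherwise uses the normal
#' approximation with tie and continuity corrections.
#'
#' @param a,b numeric samples (each non-empty).
#' @param exact_limit use an exact p when `n_a * n_b` is at most this.
#' @return an object of class `group_comparison` with fields `mean_a`,
#'   `mean_b`, `n_a`, `n_b`, `U`, `p`, `method`.
#' @export
mann_whitney_u <- function(a, b, exact_limit = 400) {
  if (!length(a) || !length(b)) stop("both groups must be non-empty")
  stopifnot(all(is.finite(a)), all(is.finite(b)))
  na <- length(a); nb <- length(b); n <- na + nb
  r <- rank(c(a, b))
  U <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  ties <- any(duplicated(c(a, b)))
  method <- NULL; p <- NA_real_
  if (na * nb <= exact_limit) {
    if (!ties) {
      counts <- u_count_distribution(na, nb)
      tot <- sum(counts)
      lo <- sum(counts[seq_len(round(U) + 1)]) / tot          # P(U <= u)
      hi <- sum(counts[(round(U) + 1):length(counts)]) / tot  # P(U >= u)
      p <- min(1, 2 * min(lo, hi))
      method <- "exact"
    } else if (choose(n, na) <= 2e5) {
      combos <- combn(n, na)
      Us <- colSums(matrix(r[combos], nrow = na)) - na * (na + 1) / 2
      eps <- 1e-9
      p <- min(1, 2 * min(mean(Us <= U + eps), mean(Us >= U - eps)))
      method <- "exact (enumeration, ties)"
    }
  }
  if (is.null(method)) {
    mu <- na * nb / 2
    tab <- table(c(a, b))
    tiecorr <- sum(tab^3 - tab) / (n * (n - 1))
    sigma <- sqrt(na * nb / 12 * ((n + 1) - tiecorr))
    z <- if (sigma > 0) (U - mu - sign(U - mu) * 0.5) / sigma else 0
    p <- min(1, 2 * pnorm(-abs(z)))
    method <- "normal approximation"
  }
  structure(list(mean_a = mean(a), mean_b = mean(b), n_a = na, n_b = nb,
                 U = U, p = p, method = method),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("Mann-Whitney U comparison (%s)\n", x$method))
  cat(sprintf("  group a: mean = %.4g (n = %d)\n", x$mean_a, x$n_a))
  cat(sprintf("  group b: mean = %.4g (n = %d)\n", x$mean_b, x$n_b))
  cat(sprintf("  U = %g, two-sided p = %.4g\n", x$U, x$p))
  invisible(x)
}

#' Compare the motility of two trajectory groups
#'
#' Computes the chosen timescale's velocity samples for each group and
#' compares them with the Mann-Whitney U test. For the exposure-interval
#' timescale, `pooling = "samples"` (default) pools every frame-to-frame
#' velocity; `pooling = "per_trajectory"` first averages within each
#' trajectory. The trajectory-time timescale always yields one sample per
#' trajectory.
#'
#' @param group_a,group_b trajectory data.frames (positions in um).
#' @param timescale `"trajectory_time"` or `"exposure_interval"`.
#' @param pooling `"samples"` or `"per_trajectory"`.
#' @return a `group_comparison` (see [mann_whitney_u()]).
#' @export
compare_motility <- function(group_a, group_b,
                             timescale = c("trajectory_time", "exposure_interval"),
                             pooling = c("samples", "per_trajectory")) {
  timescale <- match.arg(timescale)
  pooling <- match.arg(pooling)
  pull <- function(traj) {
    if (timescale == "trajectory_time") {
      trajectory_velocity(traj)$value
    } else {
      fv <- frame_velocities(traj)
      if (pooling == "per_trajectory")
        vapply(split(fv$value, fv$traj_id), mean, 0) else fv$value
    }
  }
  mann_whitney_u(pull(group_a), pull(group_b))
}

#' Velocity histogram with left-closed, right-open bins starting at 0
#'
#' @param samples numeric vector or data.frame with a `value` column.
#' @param bin_width bin width in the samples' units (> 0).
#' @return list with `edges` (length `nbins + 1`) and `counts` (summing to
#'   the sample count).
#' @export
velocity_histogram <- function(samples, bin_width) {
  if (bin_width <= 0) stop("bin_width must be > 0")
  v <- if (is.data.frame(samples)) samples$value else samples
  nbins <- if (!length(v)) 1L else max(1L, floor(max(v) / bin_width) + 1L)
  counts <- if (!length(v)) rep(0L, nbins) else
    tabulate(pmin(floor(v / bin_width) + 1L, nbins), nbins)
  list(edges = seq(0, by = bin_width, length.out = nbins + 1), counts = counts)
}

#' Per-trajectory motility metrics table
#'
#' @param traj a trajectory data.frame in um.
#' @return data.frame with `traj_id`, `n_points`, `duration_s`,
#'   `mean_frame_velocity`, `trajectory_velocity` (um/s).
#' @export
trajectory_metrics <- function(traj) {
  if (!nrow(traj))
    return(data.frame(traj_id = integer(), n_points = integer(),
                      duration_s = numeric(), mean_frame_velocity = numeric(),
                      trajectory_velocity = numeric()))
  fv <- frame_velocities(traj)
  tv <- trajectory_velocity(traj)
  parts <- split_trajs(traj)
  out <- do.call(rbind, lapply(parts, function(s) {
    id <- s$traj_id[1]
    data.frame(traj_id = id, n_points = nrow(s),
               duration_s = max(s$t) - min(s$t),
               mean_frame_velocity = mean(fv$value[fv$traj_id == id]),
               trajectory_velocity = tv$value[tv$traj_id == id])
  }))
  rownames(out) <- NULL
  out
}
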