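#' Linking parameters
#'
#' Defaults are the tracker settings used for contractile-vacuole tracking:
#' Linking range = 3, Displacement = 10. `linking_range` is the maximum
#' look-ahead when re-acquiring a lost object, i.e. a trajectory may bridge
#' up to `linking_range - 1` consecutive missed frames. `max_displacement`
#' bounds the displacement of a single linked step; across a gap of `g`
#' frames the budget is `max_displacement * g` when `scale_gap = TRUE`
#' (constant-velocity assumption) and constant otherwise.
#'
#' @param linking_range frames (>= 1).
#' @param max_displacement px per linked step (> 0).
#' @param scale_gap logical; scale the displacement budget with gap length.
#' @export
link_params <- function(linking_range = 3, max_displacement = 10,
                        scale_gap = TRUE) {
  if (linking_range < 1) stop("linking_range must be >= 1")
  if (max_displacement <= 0) stop("max_displacement must be > 0")
  structure(list(linking_range = as.integer(linking_range),
                 max_displacement = max_displacement,
                 scale_gap = isTRUE(scale_gap)),
            class = "link_params")
}

#' Link per-frame detections into trajectories
#'
#' Frame by frame, detections are assigned to open trajectories by an
#' optimal assignment (Hungarian) minimizing the total squared displacement
#' over feasible pairs; unmatched detections start new trajectories.
#' Trajectories unmatched at the immediate next frame stay open for gap
#' closing: for gaps `g = 2 .. linking_range`, remaining detections are
#' matched to trajectories last seen `g` frames ago with a displacement
#' budget of `max_displacement * g` (direct, gap-1 links always take
#' precedence over gap closing). Determinism: detections and open
#' trajectories are processed in (frame, then lower y, then lower x) order,
#' which also fixes tie-breaking in the assignment.
#'
#' @param detections data.frame with columns `frame` (integer), `x`, `y`.
#' @param p a [link_params()] object.
#' @param dt frame interval (s), used to fill the `t` column.
#' @return a trajectory data.frame (`traj_id`, `frame`, `t`, `x`, `y`) in
#'   pixel units; zero rows when there are no detections.
#' @export
link <- function(detections, p = link_params(), dt = 1) {
  empty <- trajectory_df(integer(), integer(), numeric(), numeric(), numeric(),
                         unit = "px")
  if (!nrow(detections)) return(empty)
  stopifnot(all(c("frame", "x", "y") %in% names(detections)))
  tracks <- list()   # each: list(frames, x, y)
  fr_range <- range(detections$frame)
  for (f in seq(fr_range[1], fr_range[2])) {
    dets <- detections[detections$frame == f, , drop = FALSE]
    dets <- dets[order(dets$y, dets$x), , drop = FALSE]
    nD <- nrow(dets)
    det_taken <- rep(FALSE, nD)
    if (length(tracks)) {
      last_frame <- vapply(tracks, function(tr) tr$frames[length(tr$frames)], 0)
      for (g in seq_len(p$linking_range)) {
        if (!nD || all(det_taken)) break
        cand <- which(last_frame == f - g)
        if (!length(cand)) next
        # deterministic ordering of open tracks by their last position
        lx <- vapply(tracks[cand], function(tr) tr$x[length(tr$x)], 0)
        ly <- vapply(tracks[cand], function(tr) tr$y[length(tr$y)], 0)
        cand <- cand[order(ly, lx)]
        lx <- vapply(tracks[cand], function(tr) tr$x[length(tr$x)], 0)
        ly <- vapply(tracks[cand], function(tr) tr$y[length(tr$y)], 0)
        free <- which(!det_taken)
        budget <- if (p$scale_gap) p$max_displacement * g else p$max_displacement
        m <- match_pairs(lx, ly, dets$x[free], dets$y[free], budget)
        for (i in seq_along(cand)) {
          if (is.na(m[i])) next
          j <- free[m[i]]
          ti <- cand[i]
          tracks[[ti]]$frames <- c(tracks[[ti]]$frames, f)
          tracks[[ti]]$x <- c(tracks[[ti]]$x, dets$x[j])
          tracks[[ti]]$y <- c(tracks[[ti]]$y, dets$y[j])
          det_taken[j] <- TRUE
        }
      }
    }
    for (j in which(!det_taken)) {
      tracks[[length(tracks) + 1]] <- list(frames = f, x = dets$x[j],
                                           y = dets$y[j])
    }
  }
  out <- do.call(rbind, lapply(seq_along(tracks), function(id) {
    tr <- tracks[[id]]
    trajectory_df(id, tr$frames, tr$frames * dt, tr$x, tr$y, unit = "px")
  }))
  attr(out, "unit") <- "px"
  out
}

#' Keep trajectories with at least `min_points` points
#'
#' @param trajs a trajectory data.frame.
#' @param min_points minimum number of points (default 3).
#' @return the filtered trajectory data.frame, original order preserved.
#' @export
filter_trajectories <- function(trajs, min_points = 3) {
  if (!nrow(trajs)) return(trajs)
  counts <- table(trajs$traj_id)
  keep_ids <- names(counts)[counts >= min_points]
  out <- trajs[as.character(trajs$traj_id) %in% keep_ids, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "unit") <- traj_unit(trajs)
  out
}
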