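# Evaluation of detections and tracks against simulated ground truth.

#' Match detections to ground truth and score precision/recall
#'
#' Per frame, detections are matched to ground-truth positions of the given
#' kind by optimal assignment with a gating radius. Precision is the matched
#' fraction of detections, recall the matched fraction of truth points; the
#' localization bias is the mean signed offset (detected minus true) of
#' matched pairs.
#'
#' @param detections data.frame with `frame`, `x`, `y`.
#' @param truth ground-truth data.frame (`object_id`, `frame`, `x_px`,
#'   `y_px`, `kind`).
#' @param kind truth kind to match against (`"vacuole"` or `"centroid"`).
#' @param match_radius gating radius, px (default 3).
#' @return list with `precision`, `recall`, `n_matched`, `bias_x`, `bias_y`,
#'   `bias` (norm of the mean offset), `rmse`.
#' @export
evaluate_detections <- function(detections, truth, kind = "vacuole",
                                match_radius = 3) {
  tr <- truth[truth$kind == kind, , drop = FALSE]
  n_det <- nrow(detections); n_true <- nrow(tr)
  dxs <- numeric(0); dys <- numeric(0)
  n_matched <- 0
  for (f in unique(tr$frame)) {
    tt <- tr[tr$frame == f, , drop = FALSE]
    dd <- detections[detections$frame == f, , drop = FALSE]
    if (!nrow(dd)) next
    m <- match_pairs(tt$x_px, tt$y_px, dd$x, dd$y, match_radius)
    hit <- !is.na(m)
    n_matched <- n_matched + sum(hit)
    dxs <- c(dxs, dd$x[m[hit]] - tt$x_px[hit])
    dys <- c(dys, dd$y[m[hit]] - tt$y_px[hit])
  }
  list(precision = if (n_det) n_matched / n_det else NA_real_,
       recall = if (n_true) n_matched / n_true else NA_real_,
       n_matched = n_matched,
       bias_x = mean(dxs), bias_y = mean(dys),
       bias = sqrt(mean(dxs)^2 + mean(dys)^2),
       rmse = sqrt(mean(dxs^2 + dys^2)))
}

#' Count identity swaps of linked trajectories against ground truth
#'
#' Each trajectory point is attributed to the nearest ground-truth object at
#' its frame (within `match_radius`); an identity swap is a change of the
#' attributed object along one trajectory.
#'
#' @param trajs linked trajectory data.frame (pixel units).
#' @param truth ground-truth data.frame.
#' @param kind truth kind the tracker follows.
#' @param match_radius attribution radius, px.
#' @return total number of identity changes across all trajectories.
#' @export
count_identity_swaps <- function(trajs, truth, kind = "vacuole",
                                 match_radius = 3) {
  tr <- truth[truth$kind == kind, , drop = FALSE]
  swaps <- 0
  for (s in split(trajs, trajs$traj_id)) {
    s <- s[order(s$frame), ]
    ids <- vapply(seq_len(nrow(s)), function(i) {
      tt <- tr[tr$frame == s$frame[i], , drop = FALSE]
      if (!nrow(tt)) return(NA_integer_)
      d2 <- (tt$x_px - s$x[i])^2 + (tt$y_px - s$y[i])^2
      j <- which.min(d2)
      if (d2[j] <= match_radius^2) as.integer(tt$object_id[j]) else NA_integer_
    }, integer(1))
    ids <- ids[!is.na(ids)]
    if (length(ids) > 1) swaps <- swaps + sum(diff(ids) != 0)
  }
  swaps
}
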