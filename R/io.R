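# CSV readers/writers for trajectories, detections and ground truth.
# Numeric formatting uses R's default 15-significant-digit character
# conversion, which round-trips doubles: write -> read -> write is
# byte-identical.

#' Write trajectories as CSV
#'
#' Columns: `traj_id`, `frame`, `t_s`, `x`, `y`, `unit`.
#'
#' @param traj a trajectory data.frame.
#' @param path output path.
#' @export
write_trajectories <- function(traj, path) {
  out <- data.frame(traj_id = traj$traj_id, frame = traj$frame, t_s = traj$t,
                    x = traj$x, y = traj$y,
                    unit = rep(traj_unit(traj), length.out = nrow(traj)))
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read trajectories from CSV
#' @param path CSV path written by [write_trajectories()].
#' @export
read_trajectories <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  out <- trajectory_df(d$traj_id, d$frame, d$t_s, d$x, d$y,
                       unit = if (nrow(d)) d$unit[1] else "px")
  out
}

#' Write detection or ground-truth tables as CSV
#' @param df a data.frame.
#' @param path output path.
#' @export
write_table_csv <- function(df, path) {
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a ground-truth CSV (`object_id`, `frame`, `x_px`, `y_px`, `kind`)
#' @param path CSV path.
#' @export
read_ground_truth <- function(path) read.csv(path, stringsAsFactors = FALSE)

#' Write a group comparison as a JSON report
#' @param gc a `group_comparison`.
#' @param path output path.
#' @export
write_group_comparison <- function(gc, path) {
  jsonlite::write_json(unclass(gc), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
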