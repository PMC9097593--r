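# Kymograph construction, front extraction, front-speed fitting and step
# detection for colony-front dynamics: a continually advancing invasion
# front yields a near-perfect linear position-time fit with no step events,
# while stepwise advance (e.g. daily fruiting waves) yields a poorer linear
# fit and discrete detected steps.

#' Build a kymograph from an image stack
#'
#' Column `t` of the kymograph is the frame-`t` mean intensity profile along
#' the chosen axis, averaged across a band of rows (for `axis = "x"`) or
#' columns (for `axis = "y"`).
#'
#' @param stack an [image_stack()].
#' @param axis `"x"` (profile along columns) or `"y"`.
#' @param band integer length-2, 0-based inclusive range of rows (`axis =
#'   "x"`) or columns (`axis = "y"`) to average over; `NULL` for the whole
#'   frame.
#' @return a `kymograph`: a position x time matrix with attributes
#'   `position_step` (px), `time_step` (s) and `pixel_size`.
#' @export
build_kymograph <- function(stack, axis = c("x", "y"), band = NULL) {
  axis <- match.arg(axis)
  d <- dim(stack$frames[[1]])
  lim <- if (axis == "x") d[1] else d[2]
  if (is.null(band)) band <- c(0, lim - 1)
  if (band[1] > band[2] || band[1] < 0 || band[2] > lim - 1)
    stop("band must be a non-empty 0-based range within the frame")
  sel <- (band[1]:band[2]) + 1
  profiles <- vapply(stack$frames, function(f) {
    if (axis == "x") colMeans(f[sel, , drop = FALSE])
    else rowMeans(f[, sel, drop = FALSE])
  }, numeric(if (axis == "x") d[2] else d[1]))
  k <- matrix(profiles, ncol = n_frames(stack))
  if (nrow(k) < 2 || ncol(k) < 2)
    stop("kymograph must be at least 2 x 2 (>= 2 positions and >= 2 frames)")
  structure(k, class = "kymograph", position_step = 1,
            time_step = stack$dt, pixel_size = stack$pixel_size)
}

#' Extract the front position over time from a kymograph
#'
#' Per time column, the front is the outermost crossing (in the direction of
#' advance) of a level set at `level` of the column's intensity range,
#' located to sub-pixel precision by linear interpolation between the
#' straddling samples. Columns with no crossing (e.g. constant intensity)
#' are flagged missing, never silently interpolated.
#'
#' @param k a `kymograph`.
#' @param level fraction of the per-column intensity range (default 0.5).
#' @param direction direction of advance: `"+"` (increasing position,
#'   outermost = largest crossing) or `"-"`.
#' @return a `front_trace` data.frame with `t_index` (0-based), `t` (s),
#'   `position` (px, `NA` when missing) and `missing`.
#' @export
extract_front <- function(k, level = 0.5, direction = c("+", "-")) {
  direction <- match.arg(direction)
  nt <- ncol(k)
  pos <- rep(NA_real_, nt)
  for (ti in seq_len(nt)) {
    v <- k[, ti]
    rng <- range(v)
    if (diff(rng) == 0) next
    lev <- rng[1] + level * diff(rng)
    s <- v - lev
    i <- which(s[-length(s)] * s[-1] <= 0 & s[-length(s)] != s[-1])
    if (!length(i)) next
    frac <- -s[i] / (s[i + 1] - s[i])
    crossings <- (i - 1) + frac
    pos[ti] <- if (direction == "+") max(crossings) else min(crossings)
  }
  out <- data.frame(t_index = seq_len(nt) - 1L,
                    t = (seq_len(nt) - 1L) * attr(k, "time_step"),
                    position = pos, missing = is.na(pos))
  attr(out, "level") <- level
  attr(out, "direction") <- direction
  class(out) <- c("front_trace", "data.frame")
  out
}

#' Fit a constant front speed by ordinary least squares
#'
#' @param trace a `front_trace` (or any data.frame with `t`, `position`,
#'   `missing`).
#' @return a `front_speed_fit` list: `speed` (position units per time unit),
#'   `intercept`, `residual_rms`, `r_squared`.
#' @export
fit_front_speed <- function(trace) {
  ok <- !trace$missing
  if (sum(ok) < 3) stop("fit_front_speed needs >= 3 non-missing points")
  fit <- lm(position ~ t, data = trace[ok, ])
  res <- resid(fit)
  sstot <- sum((trace$position[ok] - mean(trace$position[ok]))^2)
  ssres <- sum(res^2)
  r2 <- if (sstot <= .Machine$double.eps * max(1, ssres)) {
    if (ssres <= .Machine$double.eps) 1 else 0
  } else 1 - ssres / sstot
  structure(list(speed = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 residual_rms = sqrt(mean(res^2)),
                 r_squared = max(0, min(1, r2))),
            class = "front_speed_fit")
}

#' @export
print.front_speed_fit <- function(x, ...) {
  cat(sprintf("front speed fit: %.4g per time unit (intercept %.4g, RMS %.3g, R^2 %.4f)\n",
              x$speed, x$intercept, x$residual_rms, x$r_squared))
  invisible(x)
}

#' Detect discrete steps in a front trace
#'
#' Greedy plateau-based change-point detection: the trace is scanned for
#' maximal plateaus (runs whose internal range is below `min_step / 2`) of
#' length at least `min_dwell`; each pair of consecutive plateaus whose
#' median positions differ by at least `min_step` is a step event, timed at
#' the midpoint between the end of one plateau and the start of the next.
#'
#' @param trace a `front_trace`; missing points are dropped.
#' @param min_step minimum step size, position units.
#' @param min_dwell minimum plateau length, points.
#' @return a data.frame with `step_time` (strictly increasing) and
#'   `step_size`; zero rows when no steps are found.
#' @export
detect_steps <- function(trace, min_step, min_dwell) {
  ok <- !trace$missing
  x <- trace$position[ok]; tt <- trace$t[ok]
  if (length(x) < 2 * min_dwell)
    stop("detect_steps needs at least 2 * min_dwell points")
  plateaus <- list()
  i <- 1L; m <- length(x)
  while (i <= m) {
    j <- i
    lo <- x[i]; hi <- x[i]
    while (j < m) {
      nlo <- min(lo, x[j + 1]); nhi <- max(hi, x[j + 1])
      if (nhi - nlo >= min_step / 2) break
      lo <- nlo; hi <- nhi; j <- j + 1L
    }
    if (j - i + 1L >= min_dwell) {
      plateaus[[length(plateaus) + 1]] <- c(i, j)
      i <- j + 1L
    } else i <- i + 1L
  }
  events <- data.frame(step_time = numeric(), step_size = numeric())
  if (length(plateaus) >= 2) {
    for (kk in seq_len(length(plateaus) - 1)) {
      p1 <- plateaus[[kk]]; p2 <- plateaus[[kk + 1]]
      size <- median(x[p2[1]:p2[2]]) - median(x[p1[1]:p1[2]])
      if (abs(size) >= min_step) {
        events <- rbind(events, data.frame(
          step_time = (tt[p1[2]] + tt[p2[1]]) / 2, step_size = size))
      }
    }
  }
  rownames(events) <- NULL
  events
}

#' Write a kymograph as a grayscale TIFF
#'
#' Intensities are affinely rescaled to `[0, 1]` for storage; the scale and
#' offset are not preserved in the file.
#'
#' @param k a `kymograph`.
#' @param path output path.
#' @export
write_kymograph_tiff <- function(k, path) {
  m <- unclass(k)
  rng <- range(m)
  m <- if (diff(rng) > 0) (m - rng[1]) / diff(rng) else m * 0
  tiff::writeTIFF(m, path, bits.per.sample = 32L)
  invisible(path)
}
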