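#' Rendering parameters for synthetic phase-contrast frames
#'
#' Emulates the appearance of amoebae in phase-contrast imaging: cell bodies
#' slightly darker than the medium, a bright halo surrounding each cell, and
#' a single dark contractile vacuole at the rear of the cell (opposite the
#' heading). Templates are evaluated analytically at real-valued centres, so
#' sub-pixel localization accuracy is testable.
#'
#' The default `noise_sd` is a tenth of the vacuole contrast magnitude —
#' peak signal-to-noise 10, the reference condition for sub-pixel spot
#' localization. Noisier acquisitions (e.g. `noise_sd` at half the vacuole
#' contrast, SNR 2) still allow reliable detection but not sub-pixel
#' precision.
#'
#' @param pixel_size micrometres per pixel (presets: 1.0 at "20x", 0.3 at "60x").
#' @param background_level background intensity (images live in `[0, 1]`).
#' @param cell_body_contrast intensity offset of the cell body (< 0: darker).
#' @param halo_contrast intensity offset of the halo (> 0: brighter).
#' @param halo_width halo ring width, px.
#' @param cell_radius cell body radius, px.
#' The vacuole sits at the cell rear along the cell's polarity axis, which
#' reorients smoothly: the axis is an exponentially smoothed average of the
#' step headings with time constant `polarity_smooth` frames (a migrating
#' cell's front-rear axis turns over minutes, not within one 5 s frame, so
#' the rear marker does not swing abruptly when the step direction jitters).
#'
#' @param pixel_size micrometres per pixel (presets: 1.0 at "20x", 0.3 at "60x").
#' @param background_level background intensity (images live in `[0, 1]`).
#' @param cell_body_contrast intensity offset of the cell body (< 0: darker).
#' @param halo_contrast intensity offset of the halo (> 0: brighter).
#' @param halo_width halo ring width, px.
#' @param cell_radius cell body radius, px.
#' @param vacuole_contrast peak intensity offset of the vacuole (< 0).
#' @param vacuole_sigma Gaussian sigma of the vacuole spot, px.
#' @param polarity_smooth time constant (frames) of the polarity axis.
#' @param noise_sd i.i.d. Gaussian pixel noise standard deviation.
#' @param seed integer seed for the noise, or `NULL`.
#' @export
render_params <- function(pixel_size = 1, background_level = 0.6,
                          cell_body_contrast = -0.12, halo_contrast = 0.08,
                          halo_width = 3, cell_radius = 10,
                          vacuole_contrast = -0.25, vacuole_sigma = 2,
                          polarity_smooth = 20,
                          noise_sd = 0.25 / 10, seed = NULL) {
  if (pixel_size <= 0) stop("pixel_size must be > 0")
  if (cell_body_contrast > 0) stop("cell_body_contrast must be <= 0 (bodies darker than background)")
  if (halo_contrast < 0) stop("halo_contrast must be >= 0 (halos brighter than background)")
  if (vacuole_contrast > 0) stop("vacuole_contrast must be <= 0 (vacuoles are dark)")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (cell_radius <= 0 || halo_width <= 0 || vacuole_sigma <= 0)
    stop("cell_radius, halo_width and vacuole_sigma must be > 0")
  if (polarity_smooth < 1) stop("polarity_smooth must be >= 1 frame")
  structure(list(pixel_size = pixel_size, background_level = background_level,
                 cell_body_contrast = cell_body_contrast,
                 halo_contrast = halo_contrast, halo_width = halo_width,
                 cell_radius = cell_radius, vacuole_contrast = vacuole_contrast,
                 vacuole_sigma = vacuole_sigma,
                 polarity_smooth = polarity_smooth, noise_sd = noise_sd,
                 seed = seed),
            class = "render_params")
}

# Per-frame polarity unit vectors for one trajectory: exponentially
# smoothed step headings (time constant `smooth` frames), falling back to
# the previous axis (then +x) when stationary/at the last frame.
traj_headings <- function(x, y, smooth = 1) {
  n <- length(x)
  hx <- numeric(n); hy <- numeric(n)
  alpha <- 1 / smooth
  cur <- NULL
  for (i in seq_len(n)) {
    if (i < n) {
      d <- c(x[i + 1] - x[i], y[i + 1] - y[i])
      nd <- sqrt(sum(d^2))
      if (nd > 1e-12) {
        u <- d / nd
        cur <- if (is.null(cur)) u else {
          v <- (1 - alpha) * cur + alpha * u
          nv <- sqrt(sum(v^2))
          if (nv > 1e-12) v / nv else cur
        }
      }
    }
    if (is.null(cur)) cur <- c(1, 0)
    hx[i] <- cur[1]; hy[i] <- cur[2]
  }
  cbind(hx, hy)
}

# Add a radially defined template to `canvas` around real-valued centre
# (cx, cy) in 0-based pixel coordinates. `fun(d)` maps distance to offset.
add_template <- function(canvas, cx, cy, support, fun) {
  H <- nrow(canvas); W <- ncol(canvas)
  r0 <- max(1, floor(cy - support) + 1); r1 <- min(H, ceiling(cy + support) + 1)
  c0 <- max(1, floor(cx - support) + 1); c1 <- min(W, ceiling(cx + support) + 1)
  if (r0 > r1 || c0 > c1) return(canvas)
  rows <- r0:r1; cols <- c0:c1
  dy <- (rows - 1) - cy; dx <- (cols - 1) - cx
  d <- sqrt(outer(dy^2, dx^2, "+"))
  canvas[rows, cols] <- canvas[rows, cols] + fun(d)
  canvas
}

render_cell <- function(canvas, cx, cy, hx, hy, rp) {
  edge <- 1  # body edge softness, px
  R <- rp$cell_radius; hw <- rp$halo_width
  rh <- R + hw / 2; sh <- hw / 2
  sup_body <- R + hw + 4 * 1
  canvas <- add_template(canvas, cx, cy, sup_body, function(d) {
    rp$cell_body_contrast * pnorm((R - d) / edge) +
      rp$halo_contrast * exp(-(d - rh)^2 / (2 * sh^2))
  })
  # vacuole at the cell rear, opposite the heading
  vx <- cx - hx * 0.6 * R; vy <- cy - hy * 0.6 * R
  canvas <- add_template(canvas, vx, vy, 4 * rp$vacuole_sigma, function(d) {
    rp$vacuole_contrast * exp(-d^2 / (2 * rp$vacuole_sigma^2))
  })
  list(canvas = canvas, vx = vx, vy = vy)
}

#' Render trajectories into a synthetic phase-contrast image stack
#'
#' Each frame is `background + dark cell disk + bright annular halo + dark
#' rear vacuole Gaussian + i.i.d. Gaussian noise`. Positions must already be
#' in pixel units (see [convert_trajectories()] for the converse); all
#' positions must fall inside the frame.
#'
#' @param trajectories a trajectory data.frame in pixel units (`x`, `y`
#'   0-based pixel coordinates).
#' @param rp a [render_params()] object.
#' @param width,height frame size in px; if `NULL`, sized to fit all
#'   positions with a guard margin of `3 * cell_radius`.
#' @param dt frame interval (s) recorded on the stack.
#' @param n_frames number of frames when `trajectories` is empty (with
#'   trajectories present, frames follow the trajectory frame range).
#' @return a list with `stack` (an [image_stack()]) and `truth`, a
#'   data.frame (`object_id`, `frame`, `x_px`, `y_px`, `kind` in
#'   centroid/vacuole) recording the rendered ground truth.
#' @export
render_stack <- function(trajectories, rp = render_params(), width = NULL,
                         height = NULL, dt = 5, n_frames = 1) {
  tr <- trajectories
  if (traj_unit(tr) == "um") stop("render_stack expects pixel-unit trajectories")
  margin <- 3 * rp$cell_radius
  if (!nrow(tr) && (is.null(width) || is.null(height)))
    stop("width and height are required to render an empty scene")
  if (is.null(width)) width <- ceiling(max(tr$x, 0) + margin) + 1
  if (is.null(height)) height <- ceiling(max(tr$y, 0) + margin) + 1
  if (any(tr$x < 0 | tr$x > width - 1 | tr$y < 0 | tr$y > height - 1)) {
    bad <- which(tr$x < 0 | tr$x > width - 1 | tr$y < 0 | tr$y > height - 1)[1]
    stop(sprintf("trajectory position outside the %d x %d frame (traj %s, frame %d: x=%.2f, y=%.2f)",
                 width, height, tr$traj_id[bad], tr$frame[bad], tr$x[bad], tr$y[bad]))
  }
  frames_idx <- if (nrow(tr)) sort(unique(tr$frame)) else 0:(n_frames - 1)
  ids <- unique(tr$traj_id)
  headings <- lapply(ids, function(id) {
    s <- tr[tr$traj_id == id, ]
    s <- s[order(s$frame), ]
    cbind(frame = s$frame, s[, c("x", "y")],
          traj_headings(s$x, s$y, smooth = rp$polarity_smooth))
  })
  names(headings) <- as.character(ids)

  truth <- list()
  frames <- with_seed(rp$seed, lapply(frames_idx, function(f) {
    canvas <- matrix(rp$background_level, nrow = height, ncol = width)
    for (id in ids) {
      hh <- headings[[as.character(id)]]
      row <- which(hh$frame == f)
      if (!length(row)) next
      res <- render_cell(canvas, hh$x[row], hh$y[row], hh$hx[row], hh$hy[row], rp)
      canvas <- res$canvas
      truth[[length(truth) + 1]] <<- data.frame(
        object_id = id, frame = f,
        x_px = c(hh$x[row], res$vx), y_px = c(hh$y[row], res$vy),
        kind = c("centroid", "vacuole"))
    }
    if (rp$noise_sd > 0) {
      canvas <- canvas + matrix(rnorm(height * width, 0, rp$noise_sd), height, width)
      canvas <- pmin(pmax(canvas, 0), 1)  # detector range clipping
    }
    canvas
  }))
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(object_id = integer(), frame = integer(), x_px = numeric(),
               y_px = numeric(), kind = character())
  truth <- truth[order(truth$frame, truth$object_id, truth$kind), ]
  rownames(truth) <- NULL
  list(stack = image_stack(frames, pixel_size = rp$pixel_size, dt = dt),
       truth = truth)
}

#' Render an advancing colony front as a synthetic low-magnification stack
#'
#' A dark (invaded) region advances over a bright background along the +x
#' axis, constant along y, with a soft (1 px) edge. `continuous` mode moves
#' the front `speed` px every frame; `stepwise` mode jumps by
#' `speed * step_period` px once per `step_period` frames and is static in
#' between, so both modes share the same net displacement.
#'
#' @param speed front speed, px/frame (>= 0).
#' @param mode `"continuous"` or `"stepwise"`.
#' @param n_frames number of frames.
#' @param rp a [render_params()] object; `background_level`,
#'   `cell_body_contrast` (depth of the invaded region), `noise_sd` and
#'   `seed` are used.
#' @param step_period frames per step in `stepwise` mode.
#' @param width,height frame size; width defaults to fit the final front
#'   position plus a margin.
#' @param start initial front x position, px.
#' @param dt frame interval (s).
#' @return list with `stack` and `truth` (`frame`, `front_x_px`).
#' @export
render_front_stack <- function(speed, mode = c("continuous", "stepwise"),
                               n_frames = 50, rp = render_params(noise_sd = 0.02),
                               step_period = 20, width = NULL, height = 40,
                               start = 8, dt = 1) {
  mode <- match.arg(mode)
  if (speed < 0) stop("front speed must be >= 0")
  tt <- 0:(n_frames - 1)
  front <- if (mode == "continuous") start + speed * tt
           else start + speed * step_period * floor(tt / step_period)
  if (is.null(width)) width <- ceiling(max(front) + 10) + 1
  if (max(front) > width - 4)
    stop("front leaves the frame before the last frame; enlarge width")
  dark <- rp$background_level + rp$cell_body_contrast
  xs <- 0:(width - 1)
  frames <- with_seed(rp$seed, lapply(seq_len(n_frames), function(i) {
    prof <- dark + (rp$background_level - dark) * pnorm(xs - front[i])
    canvas <- matrix(prof, nrow = height, ncol = width, byrow = TRUE)
    if (rp$noise_sd > 0) {
      canvas <- canvas + matrix(rnorm(height * width, 0, rp$noise_sd), height, width)
      canvas <- pmin(pmax(canvas, 0), 1)  # detector range clipping
    }
    canvas
  }))
  list(stack = image_stack(frames, pixel_size = rp$pixel_size, dt = dt),
       truth = data.frame(frame = tt, front_x_px = front))
}
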