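# Configuration and the two end-to-end pipelines (cell tracking and
# contractile-vacuole spot tracking), plus the simulation entry point.

#' Default pipeline configuration
#'
#' All defaults equal the values used in the original tracking protocols:
#' frame interval 5 s; cell pipeline background kernel radius 35 px; spot
#' pipeline log offset 0.01, rolling ball radius 9 px, blur sigma 2 px,
#' detection Radius 7 / Cutoff 0 / Percentile 0.4; Linking range 3,
#' Displacement 10. `pixel_size` has no authoritative published value and
#' is therefore always an explicit calibration input (presets: 1.0 um/px at
#' "20x", 0.3 um/px at "60x").
#'
#' @param pixel_size micrometres per pixel.
#' @return a nested list of parameters.
#' @export
default_config <- function(pixel_size = 1.0) {
  list(
    pixel_size = pixel_size,
    dt = 5,
    cell = list(bg_radius = 35, min_area = 20),
    spot = list(eps = 0.01, ball_radius = 9, blur_sigma = 2,
                radius = 7, cutoff = 0, percentile = 0.4),
    link = list(linking_range = 3, max_displacement = 10, scale_gap = TRUE),
    metrics = list(min_points = 3, bin_width = 0.05),
    seed = 1
  )
}

#' Read a YAML configuration, merged over the defaults
#'
#' Keys present in the file override the defaults; everything else keeps its
#' default value, so a config file only needs to state deviations.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @export
read_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    cfg <- modifyList(cfg, yaml::read_yaml(path))
  }
  cfg
}

#' Write a fully resolved configuration as YAML
#' @param config a configuration list.
#' @param path output path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

resolve_stack <- function(stack, config) {
  if (inherits(stack, "image_stack")) return(stack)
  read_stack_tiff(stack, pixel_size = config$pixel_size, dt = config$dt)
}

write_pipeline_outputs <- function(out_dir, trajs, metrics, config) {
  if (is.null(out_dir)) return(invisible(NULL))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_trajectories(trajs, file.path(out_dir, "trajectories.csv"))
  write_table_csv(metrics, file.path(out_dir, "metrics.csv"))
  write_config(config, file.path(out_dir, "config.yaml"))
  invisible(NULL)
}

finish_pipeline <- function(detections, config, stack) {
  lp <- link_params(config$link$linking_range, config$link$max_displacement,
                    config$link$scale_gap)
  trajs <- link(detections, lp, dt = stack$dt)
  trajs <- filter_trajectories(trajs, min_points = config$metrics$min_points)
  trajs_um <- convert_trajectories(trajs, stack$pixel_size)
  metrics <- trajectory_metrics(trajs_um)
  list(trajectories = trajs_um, trajectories_px = trajs, metrics = metrics,
       detections = detections)
}

#' Run the cell-shape tracking pipeline
#'
#' `cell_preprocess` -> per-frame Otsu thresholding and centroid extraction
#' -> linking -> length filtering -> per-trajectory metrics.
#'
#' @param stack an [image_stack()] or a path to a multi-page TIFF.
#' @param config a configuration list (see [default_config()]).
#' @param out_dir if non-NULL, write `trajectories.csv`, `metrics.csv` and
#'   the fully resolved `config.yaml` there.
#' @return list with `trajectories` (um), `trajectories_px`, `metrics`,
#'   `detections`.
#' @export
run_cell_pipeline <- function(stack, config = default_config(), out_dir = NULL) {
  stack <- resolve_stack(stack, config)
  pre <- cell_preprocess(stack, radius = config$cell$bg_radius)
  detections <- detect_cells_stack(pre, min_area = config$cell$min_area)
  res <- finish_pipeline(detections, config, stack)
  write_pipeline_outputs(out_dir, res$trajectories, res$metrics, config)
  res
}

#' Run the contractile-vacuole spot tracking pipeline
#'
#' `spot_preprocess` -> sub-pixel spot detection -> linking -> length
#' filtering -> per-trajectory metrics.
#'
#' @inheritParams run_cell_pipeline
#' @return list with `trajectories` (um), `trajectories_px`, `metrics`,
#'   `detections`.
#' @export
run_spot_pipeline <- function(stack, config = default_config(), out_dir = NULL) {
  stack <- resolve_stack(stack, config)
  pre <- spot_preprocess(stack, eps = config$spot$eps,
                         ball_radius = config$spot$ball_radius,
                         blur_sigma = config$spot$blur_sigma)
  sp <- spot_params(radius = config$spot$radius, cutoff = config$spot$cutoff,
                    percentile = config$spot$percentile)
  detections <- detect_spots_stack(pre, p = sp)
  res <- finish_pipeline(detections, config, stack)
  write_pipeline_outputs(out_dir, res$trajectories, res$metrics, config)
  res
}

#' Simulate a preset scenario and write stack plus ground truth
#'
#' Scenarios map to preset motion regimes: `lobose` (directed single cells),
#' `filose` (frequently reorienting single cells), `chain` (leader-follower
#' collective), `front_continuous` and `front_stepwise` (advancing colony
#' front for kymograph analysis).
#'
#' @param scenario scenario name.
#' @param config configuration list; `seed`, `dt` and `pixel_size` are used.
#' @param out_dir if non-NULL, write `stack.tif`, `truth.csv`, `config.yaml`.
#' @param n_cells number of cells (cell scenarios).
#' @param n_frames number of frames.
#' @return list with `stack` and `truth`.
#' @export
run_simulate <- function(scenario, config = default_config(), out_dir = NULL,
                         n_cells = 5, n_frames = 100) {
  scenarios <- c("lobose", "filose", "chain", "front_continuous",
                 "front_stepwise")
  if (!scenario %in% scenarios)
    stop("unknown scenario '", scenario, "'; available: ",
         paste(scenarios, collapse = ", "))
  seed <- config$seed
  rp <- render_params(pixel_size = config$pixel_size,
                      seed = derive_seed(seed, 0, 9))
  res <- switch(scenario,
    lobose = simulate_spot_benchmark(n_cells = n_cells, n_frames = n_frames,
                                     speed = 0.25, persistence = 0.9,
                                     dt = config$dt, rp = rp, seed = seed),
    filose = simulate_spot_benchmark(n_cells = n_cells, n_frames = n_frames,
                                     speed = 0.10, persistence = 0.2,
                                     dt = config$dt, rp = rp, seed = seed),
    chain = {
      cp <- chain_params(
        n_cells = max(2, n_cells),
        leader = motion_params(speed = 0.2, persistence = 0.95, dt = config$dt,
                               n_steps = n_frames - 1,
                               seed = derive_seed(seed, 1)),
        spacing = 5, follow_gain = 0.1)
      trajs <- simulate_chain(cp)
      trajs_px <- trajs
      trajs_px$x <- trajs$x / rp$pixel_size
      trajs_px$y <- trajs$y / rp$pixel_size
      attr(trajs_px, "unit") <- "px"
      margin <- 3 * rp$cell_radius
      trajs_px$x <- trajs_px$x - min(trajs_px$x) + margin
      trajs_px$y <- trajs_px$y - min(trajs_px$y) + margin
      r <- render_stack(trajs_px, rp, dt = config$dt)
      list(stack = r$stack, truth = r$truth)
    },
    front_continuous = {
      rp$noise_sd <- 0.02; rp$cell_body_contrast <- -0.3
      render_front_stack(speed = 2, mode = "continuous", n_frames = n_frames,
                         rp = rp, dt = 1)
    },
    front_stepwise = {
      rp$noise_sd <- 0.02; rp$cell_body_contrast <- -0.3
      render_front_stack(speed = 2, mode = "stepwise", n_frames = n_frames,
                         rp = rp, step_period = max(5, n_frames %/% 4), dt = 1)
    })
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_stack_tiff(res$stack, file.path(out_dir, "stack.tif"))
    write_table_csv(res$truth, file.path(out_dir, "truth.csv"))
    write_config(config, file.path(out_dir, "config.yaml"))
  }
  res
}
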