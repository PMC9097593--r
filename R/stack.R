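#' Image stack container
#'
#' A time-lapse of equally sized grayscale frames with spatial calibration
#' (`pixel_size`, micrometres per pixel) and a fixed frame interval (`dt`,
#' seconds). This is the common currency of all imaging operations.
#'
#' Coordinate convention, used across the whole package and in all CSV
#' output: `x` is the column and `y` the row, both 0-based with pixel centres
#' at integer coordinates, so the image domain is `[0, W) x [0, H)`.
#'
#' @param frames a numeric `H x W` matrix, a list of such matrices, or a 3-D
#'   array with dimensions `H x W x T`.
#' @param pixel_size micrometres per pixel (> 0).
#' @param dt frame interval in seconds (> 0).
#' @return an object of class `image_stack`.
#' @export
image_stack <- function(frames, pixel_size = 1, dt = 5) {
  if (is.matrix(frames)) frames <- list(frames)
  if (is.array(frames) && length(dim(frames)) == 3) {
    frames <- lapply(seq_len(dim(frames)[3]), function(i) frames[, , i])
  }
  stopifnot(is.list(frames), length(frames) >= 1)
  d <- dim(frames[[1]])
  for (f in frames) {
    if (!is.matrix(f) || !identical(dim(f), d))
      stop("all frames must be matrices of identical dimensions")
    if (!all(is.finite(f))) stop("frames must contain finite values only")
  }
  if (!is.numeric(pixel_size) || pixel_size <= 0) stop("pixel_size must be > 0")
  if (!is.numeric(dt) || dt <= 0) stop("dt must be > 0")
  structure(list(frames = frames, pixel_size = pixel_size, dt = dt),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("<image_stack> %d frames of %d x %d px, %.3g um/px, dt = %g s\n",
              length(x$frames), d[1], d[2], x$pixel_size, x$dt))
  invisible(x)
}

#' Number of frames in a stack
#' @param stack an `image_stack`.
#' @export
n_frames <- function(stack) length(stack$frames)

#' Extract one frame (matrix) from a stack
#' @param stack an `image_stack`.
#' @param i frame index, 1-based.
#' @export
stack_frame <- function(stack, i) stack$frames[[i]]

# Apply a per-frame image operator to every frame of a stack.
map_frames <- function(stack, f, ...) {
  out <- stack
  out$frames <- lapply(stack$frames, f, ...)
  out
}

#' Write an image stack as a multi-page 32-bit float grayscale TIFF
#'
#' @param stack an `image_stack`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_stack_tiff <- function(stack, path) {
  tiff::writeTIFF(stack$frames, path, bits.per.sample = 32L)
  invisible(path)
}

#' Read a multi-page grayscale TIFF as an image stack
#'
#' TIFF files carry no calibration the package trusts, so `pixel_size` and
#' `dt` are always explicit inputs.
#'
#' @param path TIFF file path.
#' @param pixel_size micrometres per pixel.
#' @param dt frame interval in seconds.
#' @export
read_stack_tiff <- function(path, pixel_size = 1, dt = 5) {
  if (!file.exists(path)) stop("stack file not found: ", path)
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = FALSE),
                    error = function(e) stop("failed to read TIFF '", path, "': ",
                                             conditionMessage(e)))
  if (is.matrix(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3) p <- p[, , 1]  # collapse accidental extra channel
    p
  })
  image_stack(pages, pixel_size = pixel_size, dt = dt)
}
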