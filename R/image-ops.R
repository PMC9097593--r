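# The two preprocessing pipelines and the five primitive operators they are
# built from. All operators are shape-preserving and deterministic, accept a
# plain matrix or an image_stack (applied per frame), and use nearest-border
# replication at image edges.

# Dispatch helper: apply `f` to a matrix or to every frame of a stack.
apply_imgop <- function(x, f) {
  if (inherits(x, "image_stack")) map_frames(x, f) else f(x)
}

# Replicate-pad a matrix by `r` pixels on every side.
pad_replicate <- function(img, r) {
  H <- nrow(img); W <- ncol(img)
  img[c(rep(1L, r), seq_len(H), rep(H, r)), c(rep(1L, r), seq_len(W), rep(W, r)),
      drop = FALSE]
}

# Linear filtering with replicate borders; `kernel` has odd dimensions.
filter_replicate <- function(img, kernel) {
  r <- (nrow(kernel) - 1L) / 2L
  padded <- pad_replicate(img, r)
  out <- EBImage::filter2(padded, kernel, boundary = "circular")
  out[(r + 1):(r + nrow(img)), (r + 1):(r + ncol(img)), drop = FALSE]
}

disk_mask <- function(radius) {
  q <- -radius:radius
  outer(q^2, q^2, "+") <= radius^2
}

#' Invert image intensities
#'
#' Multiplies every pixel by -1 (LUT inversion for computation): dark
#' objects become bright, which is what downstream thresholding and maxima
#' detection expect.
#'
#' @param x a matrix or [image_stack()].
#' @export
img_invert <- function(x) apply_imgop(x, function(img) -img)

#' Offset log transform
#'
#' `log(x + eps)`, with a small offset so zero-intensity pixels do not
#' diverge.
#'
#' @param x a matrix or [image_stack()].
#' @param eps intensity offset added before the log (default 0.01).
#' @export
log_offset <- function(x, eps = 0.01) {
  apply_imgop(x, function(img) {
    bad <- which(img + eps <= 0)
    if (length(bad)) {
      rc <- arrayInd(bad[1], dim(img))
      stop(sprintf(
        "log_offset: pixel at row %d, col %d has value %.6g; value + eps = %.6g <= 0",
        rc[1], rc[2], img[bad[1]], img[bad[1]] + eps))
    }
    log(img + eps)
  })
}

#' Local background subtraction by a circular mean filter
#'
#' Subtracts, at every pixel, the mean intensity over a circular
#' neighbourhood of the given radius (nearest-border replication at edges).
#' Used by the cell pipeline with its characteristic radius of 35 px to make
#' cell bodies stand out against slowly varying illumination.
#'
#' @param x a matrix or [image_stack()].
#' @param radius neighbourhood radius, px (>= 1; default 35).
#' @export
local_background_subtract <- function(x, radius = 35) {
  if (!is.numeric(radius) || radius < 1) stop("radius must be >= 1")
  mask <- disk_mask(radius)
  kernel <- mask / sum(mask)
  apply_imgop(x, function(img) img - filter_replicate(img, kernel))
}

# Spherical-cap structuring element for the rolling ball, heights in
# intensity units of range/255 (the classic 8-bit behaviour carried over to
# float images: a radius-9 ball on 0..255 data is a shallow cap relative to
# the signal, and the same relative geometry is kept here).
ball_se <- function(radius, intensity_range) {
  q <- -floor(radius):floor(radius)
  d2 <- outer(q^2, q^2, "+")
  se <- matrix(NA_real_, length(q), length(q))
  inside <- d2 <= radius^2
  se[inside] <- sqrt(radius^2 - d2[inside]) * (intensity_range / 255)
  se
}

#' Rolling-ball background subtraction
#'
#' Estimates the background as the grey opening of the image by a
#' ball-shaped (spherical cap) structuring element of the given radius and
#' subtracts it. The cap height profile is expressed in intensity levels of
#' `range(image)/255`, reproducing the classic algorithm's behaviour on
#' 8-bit data for float images: features narrower than the ball's 2*radius
#' support are kept, broader background structure is removed. The background
#' estimate is everywhere <= the image, so the output is >= 0.
#'
#' @param x a matrix or [image_stack()].
#' @param radius ball radius, px (>= 1; default 9).
#' @export
rolling_ball_subtract <- function(x, radius = 9) {
  if (!is.numeric(radius) || radius < 1) stop("radius must be >= 1")
  apply_imgop(x, function(img) {
    rng <- diff(range(img))
    if (rng == 0) return(img - img[1])
    se <- ball_se(radius, rng)
    bg <- grey_morph(grey_morph(img, se, FALSE), se, TRUE)
    img - bg
  })
}

gaussian_kernel <- function(sigma) {
  r <- max(1L, as.integer(ceiling(4 * sigma)))
  q <- -r:r
  k <- exp(-outer(q^2, q^2, "+") / (2 * sigma^2))
  k / sum(k)
}

#' Gaussian blur
#'
#' Convolution with a normalized 2-D Gaussian (replicate borders). The spot
#' pipeline uses sigma = 2 px to make vacuoles look like smooth spots.
#'
#' @param x a matrix or [image_stack()].
#' @param sigma Gaussian standard deviation, px (> 0).
#' @export
gaussian_blur <- function(x, sigma = 2) {
  if (!is.numeric(sigma) || sigma <= 0) stop("sigma must be > 0")
  kernel <- gaussian_kernel(sigma)
  apply_imgop(x, function(img) filter_replicate(img, kernel))
}

#' Cell-shape preprocessing pipeline
#'
#' Per frame: intensity inversion, then local background subtraction with a
#' 35 px kernel radius. Dark-bodied cells with bright halos become bright,
#' well-defined shapes on a flat background, ready for thresholding.
#'
#' @param stack an [image_stack()] (or single matrix).
#' @param radius background subtraction radius, px.
#' @export
cell_preprocess <- function(stack, radius = 35) {
  local_background_subtract(img_invert(stack), radius = radius)
}

#' Vacuole spot preprocessing pipeline
#'
#' Per frame: add 0.01 and log-transform, invert by multiplication by -1,
#' rolling-ball background subtraction (radius 9), then Gaussian blur
#' (sigma 2). Dark contractile vacuoles become bright, spot-like maxima.
#'
#' @param stack an [image_stack()] (or single matrix).
#' @param eps offset added before the log transform.
#' @param ball_radius rolling-ball radius, px.
#' @param blur_sigma Gaussian blur sigma, px.
#' @export
spot_preprocess <- function(stack, eps = 0.01, ball_radius = 9, blur_sigma = 2) {
  gaussian_blur(
    rolling_ball_subtract(
      img_invert(log_offset(stack, eps = eps)),
      radius = ball_radius),
    sigma = blur_sigma)
}
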