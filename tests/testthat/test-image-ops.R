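# Primitive operators and the two preprocessing pipelines.

test_that("inversion negates pointwise and is an involution", {
  m <- matrix(c(1, -2, 0, 3), 2, 2, byrow = TRUE)
  expect_equal(img_invert(m), -m)
  expect_equal(img_invert(img_invert(m)), m)
  expect_equal(img_invert(matrix(4, 3, 3)), matrix(-4, 3, 3))
})

test_that("log_offset matches closed forms and preserves order", {
  expect_equal(log_offset(matrix(0, 1, 1))[1, 1], log(0.01), tolerance = 1e-10)
  expect_equal(log_offset(matrix(exp(1) - 0.01, 1, 1))[1, 1], 1.0,
               tolerance = 1e-10)
  set.seed(1)
  a <- matrix(runif(25), 5, 5); b <- a + 0.1
  expect_true(all(log_offset(b) > log_offset(a)))
})

test_that("log_offset rejects non-positive offsets with the pixel location", {
  m <- matrix(0.5, 3, 4); m[2, 3] <- -0.5
  expect_error(log_offset(m), "row 2, col 3")
})

test_that("local background subtraction zeroes constants and flattens ramps", {
  expect_equal(local_background_subtract(matrix(3, 20, 30), 5),
               matrix(0, 20, 30), tolerance = 1e-10)
  # slowly varying ramp: interior output approximately zero-mean
  ramp <- matrix(rep(seq(0, 1, length.out = 60), each = 50), 50, 60)
  out <- local_background_subtract(ramp, 5)
  interior <- out[11:40, 11:50]
  expect_lt(abs(mean(interior)), 1e-6)
})

test_that("local background subtraction of an impulse matches the disk-count form", {
  radius <- 5
  A <- sum(disk_mask_count <- {
    q <- -radius:radius
    outer(q^2, q^2, "+") <= radius^2
  })
  img <- matrix(0, 41, 41); img[21, 21] <- 2
  out <- local_background_subtract(img, radius)
  expect_equal(out[21, 21], 2 * (1 - 1 / A), tolerance = 1e-9)
})

test_that("local background subtraction agrees with a direct mean filter", {
  set.seed(4)
  img <- matrix(runif(20 * 24), 20, 24)
  expect_equal(local_background_subtract(img, 3),
               img - naive_disk_mean(img, 3), tolerance = 1e-9)
  expect_error(local_background_subtract(img, 0), "radius")
})

test_that("rolling ball zeroes constants and preserves a narrow peak", {
  expect_equal(rolling_ball_subtract(matrix(2, 20, 20), 9),
               matrix(0, 20, 20))
  img <- gaussian_spot_frame(60, 60, 30, 30, sigma = 2, peak = 0.5) + 0.1
  out <- rolling_ball_subtract(img, 9)
  expect_lt(abs(max(out) - 0.5) / 0.5, 0.10)          # peak height kept
  expect_lt(max(abs(out[1:10, 1:10])), 0.005)          # background residual < 1% of peak
  expect_true(all(out >= -1e-12))                      # opening <= image
})

test_that("gaussian blur preserves constants, impulse peak and total intensity", {
  expect_equal(gaussian_blur(matrix(5, 15, 15), 2), matrix(5, 15, 15),
               tolerance = 1e-10)
  imp <- matrix(0, 41, 41); imp[21, 21] <- 1
  out <- gaussian_blur(imp, 2)
  expect_equal(max(out), 1 / (2 * pi * 4), tolerance = 1e-4)
  expect_equal(which.max(out), which.max(imp))
  # interior-supported input: total conserved
  expect_equal(sum(out), 1, tolerance = 1e-6)
  expect_error(gaussian_blur(imp, 0), "sigma")
})

test_that("cell pipeline turns dark cells into the brightest region", {
  rp <- render_params(noise_sd = 0)
  tr <- data.frame(traj_id = 1L, frame = 0L, t = 0, x = 45, y = 35)
  attr(tr, "unit") <- "px"
  r <- render_stack(tr, rp, width = 100, height = 80)
  pre <- cell_preprocess(r$stack)
  f <- pre$frames[[1]]
  mx <- arrayInd(which.max(f), dim(f))
  # brightest pixel lies inside the cell body
  expect_lt(sqrt((mx[2] - 1 - 45)^2 + (mx[1] - 1 - 35)^2), rp$cell_radius)
  # constant stack maps to zero
  zero <- cell_preprocess(image_stack(matrix(0.7, 40, 40)))
  expect_equal(zero$frames[[1]], matrix(0, 40, 40), tolerance = 1e-10)
})

test_that("pipeline operator order is locked by regression", {
  # cell pipeline: negation and the linear mean filter commute exactly, so
  # the composition equals the stated order by construction
  ramp <- matrix(rep(seq(0.2, 0.8, length.out = 40), each = 30), 30, 40)
  expect_equal(cell_preprocess(image_stack(ramp), radius = 5)$frames[[1]],
               local_background_subtract(img_invert(ramp), 5))
  # spot pipeline: the order is sharply non-commutative — log must precede
  # inversion (the swapped order feeds negatives into the log and is
  # rejected), and background subtraction must precede the blur
  set.seed(2)
  img <- matrix(runif(30 * 40, 0.3, 0.5), 30, 40)
  expect_error(log_offset(img_invert(img)), "log_offset")
  a <- gaussian_blur(rolling_ball_subtract(img_invert(log_offset(img)), 9), 2)
  b <- rolling_ball_subtract(gaussian_blur(img_invert(log_offset(img)), 2), 9)
  expect_false(isTRUE(all.equal(a, b)))
  expect_equal(spot_preprocess(image_stack(img))$frames[[1]], a)
})

test_that("spot pipeline raises vacuoles as bright maxima with sub-pixel accuracy", {
  rp <- render_params(noise_sd = 0)
  tr <- data.frame(traj_id = 1L, frame = 0:1, t = c(0, 5), x = c(45, 46), y = 35)
  attr(tr, "unit") <- "px"
  r <- render_stack(tr, rp, width = 100, height = 80)
  pre <- spot_preprocess(r$stack)
  f <- pre$frames[[1]]
  vac <- r$truth[r$truth$kind == "vacuole" & r$truth$frame == 0, ]
  mx <- arrayInd(which.max(f), dim(f))
  expect_lt(sqrt((mx[2] - 1 - vac$x_px)^2 + (mx[1] - 1 - vac$y_px)^2), 1.5)
  # constant positive stack maps to zero
  zero <- spot_preprocess(image_stack(matrix(0.5, 40, 40)))
  expect_lt(max(abs(zero$frames[[1]])), 1e-10)
})

test_that("deeper vacuoles give higher processed peaks (monotone contrast)", {
  tr <- data.frame(traj_id = 1L, frame = 0L, t = 0, x = 45, y = 35)
  attr(tr, "unit") <- "px"
  peaks <- vapply(c(-0.15, -0.3), function(vc) {
    rp <- render_params(noise_sd = 0, vacuole_contrast = vc)
    r <- render_stack(tr, rp, width = 100, height = 80)
    max(spot_preprocess(r$stack)$frames[[1]])
  }, 0)
  expect_gt(peaks[2], peaks[1])
})

test_that("background subtraction and blur commute with integer translation (interior)", {
  set.seed(8)
  base <- matrix(0.3, 60, 60)
  base[25:32, 28:35] <- base[25:32, 28:35] + 0.4
  shifted <- matrix(0.3, 60, 60)
  base_sm <- gaussian_blur(base, 1.5)
  shifted[(25:32) + 4, (28:35) + 6] <- shifted[(25:32) + 4, (28:35) + 6] + 0.4
  shifted_sm <- gaussian_blur(shifted, 1.5)
  for (f in list(function(m) local_background_subtract(m, 6),
                 function(m) rolling_ball_subtract(m, 6),
                 function(m) gaussian_blur(m, 2))) {
    a <- f(base_sm); b <- f(shifted_sm)
    expect_equal(a[20:40, 20:40], b[(20:40) + 4, (20:40) + 6], tolerance = 1e-8)
  }
})
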