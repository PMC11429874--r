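test_that("well-separated bright spots are localized to subpixel accuracy", {
  sc <- scene_spec(field_size = 13)
  cam <- camera_model()
  # 20 spots on a staggered grid, SNR ~ 10
  tr <- data.frame(
    x_um = as.vector(outer(seq(1.5, 11.5, length.out = 5), rep(1, 4))),
    y_um = as.vector(outer(rep(1, 5), seq(1.8, 11.2, length.out = 4))),
    intensity = intensity_for_snr(10, sc, cam))
  img <- render_frame(tr, sc, cam, seed = 31)
  det <- detect_spots(img, sc)
  expect_equal(nrow(det), 20)
  m <- match_detections(det, tr, tol_um = 0.5 * sc$pixel_size)
  expect_equal(m$tp, 20) # every truth matched within 0.5 px
  expect_lt(abs(mean(det$intensity) / tr$intensity[1] - 1), 0.05)
})

test_that("a noiseless rendered spot is recovered exactly", {
  sc <- scene_spec(field_size = 5)
  tr <- data.frame(x_um = 2.43, y_um = 2.61, intensity = 800)
  img <- render_frame(tr, sc, camera_model(offset = 100, read_noise_sd = 0),
                      shot_noise = FALSE, read_noise = FALSE)
  det <- detect_spots(img, sc)
  expect_equal(nrow(det), 1)
  expect_lt(abs(det$intensity / 800 - 1), 0.01)
  expect_lt(abs(det$x_um - 2.43), 0.1 * sc$pixel_size)
  expect_lt(abs(det$y_um - 2.61), 0.1 * sc$pixel_size)
})

test_that("blank frames produce almost no false positives", {
  sc <- scene_spec(field_size = 13)
  cam <- camera_model()
  set.seed(32)
  fp <- vapply(1:25, function(i)
    nrow(detect_spots(render_frame(NULL, sc, cam), sc)), numeric(1))
  expect_lt(mean(fp) / prod(sc$field_size) * 100, 0.05)
})

test_that("density counting is exact and additive over disjoint ROIs", {
  expect_equal(count_density(data.frame(frame = integer(0),
                                        x_um = numeric(0),
                                        y_um = numeric(0)),
                             roi_rect(0, 0, 10, 10))$density, 0)

  set.seed(33)
  spots <- data.frame(frame = 1L, x_um = runif(25, 0, 10),
                      y_um = runif(25, 0, 10))
  expect_equal(count_density(spots, roi_rect(0, 0, 10, 10))$density, 25)

  expect_error(roi_rect(0, 0, -1, 10)) # zero/negative area is rejected
  expect_error(roi_mask(matrix(FALSE, 4, 4), 0.1), "empty")

  # additivity: two disjoint halves sum to the whole (after area weighting)
  left <- roi_rect(0, 0, 5, 10)
  right <- roi_rect(5, 0, 5, 10)
  whole <- roi_rect(0, 0, 10, 10)
  n_left <- count_density(spots, left)$density * left$area / 100
  n_right <- count_density(spots, right)$density * right$area / 100
  n_whole <- count_density(spots, whole)$density * whole$area / 100
  expect_equal(n_left + n_right, n_whole)

  # mask ROI agrees with the equivalent rectangle
  mask <- matrix(FALSE, 120, 120)
  mask[1:58, 1:58] <- TRUE # 58 px * 0.0867 um ~ first 5.03 um
  rm <- roi_mask(mask, pixel_size = 0.0867)
  inside <- spots$x_um < 58 * 0.0867 & spots$y_um < 58 * 0.0867
  expect_equal(count_density(spots, rm)$density * rm$area / 100, sum(inside))
})

test_that("rolling averages respect the window and edge conventions", {
  t20 <- seq(0, 14.95, by = 0.05) / 60 # 20 Hz, minutes

  const <- time_series(t20, rep(3, length(t20)))
  expect_equal(rolling_average(const, window = 5,
                               frame_interval = 0.05)$value,
               const$value)

  ramp <- time_series(t20, seq_along(t20))
  expect_equal(rolling_average(ramp, window = 0.05,
                               frame_interval = 0.05)$value, ramp$value)
  expect_warning(rolling_average(ramp, window = 0.01,
                                 frame_interval = 0.05), "window")

  # 20 Hz unit step smoothed over 5 s: ramp spans exactly 100 samples
  step <- time_series(t20, as.numeric(seq_along(t20) > 150))
  sm <- rolling_average(step, window = 5, frame_interval = 0.05)$value
  in_ramp <- which(sm > 0 & sm < 1)
  expect_equal(length(in_ramp), 99) # 100-sample transition has 99 interior
  # direct mean oracle at an arbitrary interior point
  i <- 120
  w <- 100
  lo <- i - ((w - 1) %/% 2)
  hi <- i + (w - 1 - (w - 1) %/% 2)
  expect_equal(sm[i], mean(step$value[lo:hi]))
})

test_that("membrane traces are background-subtracted and baseline-normalized", {
  # uniform frames: zero net intensity, flagged instead of divided
  frames <- replicate(6, matrix(120, 40, 40), simplify = FALSE)
  expect_warning(
    tr <- measure_membrane_trace(frames, roi_rect(0, 0, 2, 2),
                                 pre_frames = 1:2, pixel_size = 0.1,
                                 frame_interval = 30),
    "zero")
  expect_true(all(tr$value == 0))
  expect_false(attr(tr, "normalized"))

  # modal background equals the configured constant offset
  set.seed(34)
  img <- matrix(100, 60, 60)
  img[20:30, 20:30] <- 180 # bright cell patch < 50% of pixels
  expect_equal(modal_intensity(img), 100)

  # normalization identity and invariance to adding a constant
  mk <- function(shift = 0) lapply(c(1, 1, 2, 4, 3), function(a) {
    m <- matrix(100, 40, 40)
    m[10:20, 10:20] <- 100 + 50 * a
    m + shift
  })
  roi <- roi_rect(0.9, 0.9, 1.2, 1.2)
  tr0 <- measure_membrane_trace(mk(), roi, pre_frames = 1:2,
                                pixel_size = 0.1, frame_interval = 30)
  expect_equal(mean(tr0$value[tr0$t < 0]), 1)
  tr_shift <- measure_membrane_trace(mk(25), roi, pre_frames = 1:2,
                                     pixel_size = 0.1, frame_interval = 30)
  expect_equal(tr_shift$value, tr0$value)
})

test_that("expression binning uses half-open bins with an overflow cohort", {
  # single covering bin reproduces the grand mean
  one <- bin_by_expression(c(10, 20, 30), c(1, 2, 3), c(0, 100))
  expect_equal(one$mean, 2)
  expect_equal(one$n, 3)

  # half-open convention: a value on the upper edge falls outside
  two <- bin_by_expression(c(50, 100), c(1, 2), c(0, 100))
  expect_equal(two$n, c(1, 1))
  expect_equal(two$bin[2], "overflow")

  expect_error(bin_by_expression(1, 1, c(10, 5)), "increasing")

  # monotone dose-response is preserved by cohort means
  set.seed(35)
  expr_lvl <- runif(400, 0, 1000)
  response <- 100 / (1 + (expr_lvl / 300)^2) + rnorm(400, sd = 2)
  cohorts <- bin_by_expression(expr_lvl, response,
                               seq(0, 1000, by = 250))
  expect_true(all(diff(cohorts$mean[1:4]) <= 0))
})
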