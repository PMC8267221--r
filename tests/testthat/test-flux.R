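# Desinusoiding, video registration, temporal-SD binning, velocimetry and
# the square-wave blood-cell detectability model.

ronchi_image <- function(width = 240L, height = 40L, pitch_px = 12,
                         distortion = NULL, noise = 0.01, seed = 1) {
  set.seed(seed)
  xs <- seq_len(width)
  if (!is.null(distortion)) xs <- distortion(xs)
  profile <- 0.5 + 0.5 * cos(2 * pi * xs / pitch_px)
  img <- matrix(rep(profile, each = height), height, width) +
    matrix(rnorm(height * width, 0, noise), height, width)
  img
}

test_that("an undistorted grid yields an identity map and its scale", {
  img <- ronchi_image(pitch_px = 12)
  map <- build_desinusoid_map(img, line_pitch_um = 10)
  expect_lt(max(abs(map$lookup - seq_len(ncol(img)))), 0.1)
  # pitch 10 um over ~12 px spacing
  expect_equal(map$scale_um_per_px, 10 / 12, tolerance = 0.01)
})

test_that("sinusoidal distortion is corrected to < 1% spacing CV", {
  width <- 240L
  distortion <- function(x) x + 6 * sin(2 * pi * x / width)
  img <- ronchi_image(distortion = distortion)
  spacing_cv <- function(im) {
    centers <- sdocta:::detect_line_centers(colMeans(im))
    sd(diff(centers)) / mean(diff(centers))
  }
  expect_gt(spacing_cv(img), 0.10)
  map <- build_desinusoid_map(img, line_pitch_um = 10)
  corrected <- apply_desinusoid(img, map)
  expect_lt(spacing_cv(corrected), 0.01)
})

test_that("too few grid lines raise an error", {
  img <- ronchi_image(width = 40L, pitch_px = 18)
  expect_error(build_desinusoid_map(img, 10), "grid lines")
})

test_that("video registration recovers injected random-walk shifts exactly", {
  set.seed(9)
  base <- gaussian_blur(matrix(runif(48 * 48), 48, 48), 1.5)
  steps <- matrix(sample(-3:3, 2 * 8, replace = TRUE), ncol = 2)
  walk <- apply(steps, 2, cumsum)
  frames <- array(0, dim = c(48, 48, 9))
  frames[, , 1] <- base
  for (f in 2:9)
    frames[, , f] <- sdocta:::shift_int(base, walk[f - 1, 1], walk[f - 1, 2])
  vid <- aoslo_video(frames, seq_len(9) / 16.6, 1)
  reg <- register_video(vid, reference_index = 1L, max_shift = 10L)
  expect_identical(reg$shifts$dr_px[-1], -walk[, 1])
  expect_identical(reg$shifts$dc_px[-1], -walk[, 2])
  # identical frames: zero shifts
  same <- aoslo_video(array(rep(base, 3), dim = c(48, 48, 3)),
                      1:3 / 16.6, 1)
  regs <- register_video(same)
  expect_true(all(regs$shifts$dr_px == 0 & regs$shifts$dc_px == 0))
})

test_that("the NCC argmax equals the brute-force correlation oracle", {
  set.seed(10)
  ref <- matrix(runif(32 * 32), 32, 32)
  mov <- sdocta:::shift_int(ref, 2, -3) +
    matrix(rnorm(32 * 32, 0, 0.01), 32, 32)
  # oracle: exhaustive overlap Pearson correlation
  rng <- -5:5
  cc <- matrix(NA_real_, 11, 11)
  for (i in 1:11) for (j in 1:11) {
    cc[i, j] <- sdocta:::ncc_int_shift(ref, mov, rng[i], rng[j])
  }
  oracle <- rng[which(cc == max(cc), arr.ind = TRUE)[1, ]]
  vid <- aoslo_video(array(c(ref, mov), dim = c(32, 32, 2)), 1:2, 1)
  reg <- register_video(vid, reference_index = 1L, max_shift = 5L)
  expect_identical(c(reg$shifts$dr_px[2], reg$shifts$dc_px[2]), oracle)
})

test_that("temporal SD bins count, vanish for static video, light up paths", {
  set.seed(11)
  static <- aoslo_video(array(rep(runif(24 * 24), 30), dim = c(24, 24, 30)),
                        seq_len(30) / 16.6, 1)
  s <- temporal_std_bins(static, 10L)
  expect_identical(dim(s)[3], 3L)
  expect_true(all(s == 0))
  expect_error(temporal_std_bins(static, 1L), "bin_size")
  g <- generate_aoslo_video(24.4, n_frames = 30, jitter_px = 0, seed = 12)
  sd3 <- temporal_std_bins(g$video, 10L)
  path_row <- round(g$track$y_px[1])
  # columns the cell actually traverses during the first bin
  cols <- round(min(g$track$x_px[1:10])):round(max(g$track$x_px[1:10]))
  on_path <- mean(sd3[path_row + (-1:1), cols, 1])
  off_path <- mean(sd3[1:5, , 1])
  expect_gt(on_path, 5 * off_path)
})

test_that("velocity estimates follow path length over elapsed time", {
  tr <- data.frame(time_s = c(0, 0.5), x_px = c(0, 10), y_px = c(0, 0))
  est <- estimate_velocity(tr, scale_um_per_px = 1)
  expect_equal(est$velocity_um_s, 20)
  expect_equal(est$fit_slope_um_s, 20)
  still <- data.frame(time_s = 0:4, x_px = rep(2, 5), y_px = rep(3, 5))
  expect_equal(estimate_velocity(still, 1)$velocity_um_s, 0)
  bad <- data.frame(time_s = c(1, 1), x_px = 1:2, y_px = 1:2)
  expect_error(estimate_velocity(bad, 1), "elapsed")
})

test_that("velocity recovery is unbiased across the physiological range", {
  for (v in c(5, 25, 100)) {
    g <- generate_aoslo_video(v, n_frames = 30, jitter_px = 0,
                              scale_um_per_px = 1,
                              width_px = if (v > 50) 384L else 128L,
                              seed = 20 + v)
    tr <- data.frame(time_s = g$track$time_s, x_px = g$track$x_px,
                     y_px = g$track$y_px)
    est <- estimate_velocity(tr, scale_um_per_px = 1)
    expect_lt(abs(est$velocity_um_s - v) / v, 0.05)
  }
})

test_that("the square-wave model derives duty, dwell and interval ratio", {
  m <- square_wave_model(8.4, 122, 24.4)
  expect_equal(round(100 * m$duty_cycle), 7)
  expect_equal(m$required_dwell_s, 5.0)
  expect_equal(interval_ratio(m, 5.03), 5.0 / 0.00503)
  # dimensionless duty: unit rescaling of L and Lambda
  m2 <- square_wave_model(8.4e3, 122e3, 24.4)
  expect_equal(m2$duty_cycle, m$duty_cycle)
  # L = Lambda -> duty 100%; doubling v halves the dwell
  expect_equal(square_wave_model(10, 10, 5)$duty_cycle, 1)
  expect_equal(square_wave_model(8.4, 122, 48.8)$required_dwell_s, 2.5)
  expect_error(square_wave_model(130, 122, 10), "exceeds")
})

test_that("occupancy probability approaches the duty cycle for short T_R", {
  m <- square_wave_model(8.4, 122, 24.4)
  p <- occupancy_probability(m, t_r_ms = 5.03, n_trials = 1e5, seed = 4)
  expect_lt(abs(p - m$duty_cycle), 0.01)
})
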