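# Digital phantom: forward interferogram model, flux-dependent
# decorrelation, en-face vasculature fixtures and AOSLO video simulation.

test_that("an empty phantom produces envelope plus noise only", {
  h <- small_header(n_samples = 256L, n_ascans = 32L, n_bscans = 1L)
  sp <- phantom_spec(layers = layers3()[0, ], vessel_layers = no_vessels(),
                     noise_sigma = 3, seed = 42)
  ph <- generate_raw_spectra(sp, h)
  fr <- get_frame(ph$volume, 1, 1)
  # no fringes: per-sample spread across A-scans is pure noise
  spread <- apply(fr, 1, sd)
  expect_lt(max(spread), 3 * 3 + 1)       # quantization widens slightly
  # and the reconstruction is noise only: far below a reflector's peak
  rec <- reconstruct_frame(remove_dc_autocorrelation(
    resample_to_k(fr, h$wavelength_calibration)))
  refl <- phantom_single_reflector(h, z_um = 120, noise_sigma = 3, seed = 42)
  rec_refl <- reconstruct_frame(remove_dc_autocorrelation(
    resample_to_k(get_frame(refl, 1, 1), h$wavelength_calibration)))
  expect_lt(max(rec[10:nrow(rec), ]), 0.1 * max(rec_refl))
})

test_that("a deep single reflector reconstructs within one axial pixel", {
  h <- small_header(n_samples = 512L, n_ascans = 32L, n_bscans = 1L)
  raw <- phantom_single_reflector(h, z_um = 400, seed = 8)
  amp <- reconstruct_frame(remove_dc_autocorrelation(
    resample_to_k(get_frame(raw, 1, 1), h$wavelength_calibration)))
  dz <- attr(amp, "z_spacing_um")
  peak_um <- (which.max(rowMeans(amp)) - 1) * dz
  expect_lt(abs(peak_um - 400), dz)
})

test_that("layer deeper than the depth range is refused", {
  h <- small_header(n_samples = 256L)   # z_max ~ 247 um
  deep <- data.frame(name = "X", depth_um = 400, thickness_um = 20,
                     reflectivity = 0.5)
  expect_error(generate_raw_spectra(
    phantom_spec(layers = deep, vessel_layers = no_vessels()), h),
    "depth range")
})

test_that("flow fraction separates vessel decorrelation by > 0.15", {
  h <- phantom_header(n_samples = 384L, n_ascans = 48L, n_bscans = 4L,
                      n_repeats = 2L)
  one_plexus <- data.frame(name = "MCP", depth_um = 150,
                           target_density_pct = 25)
  d_mean <- function(flow) {
    sp <- phantom_spec(layers = layers3(), vessel_layers = one_plexus,
                       flow_fraction = flow, noise_sigma = 3, seed = 77)
    ph <- generate_raw_spectra(sp, h)
    vol <- reconstruct_volume(ph$volume)
    mean(vapply(1:4, function(b)
      vessel_voxel_decorrelation(ph, vol, b), 0))
  }
  expect_gt(d_mean(1) - d_mean(0), 0.15)
})

test_that("frozen flow leaves vessels at the noise-floor decorrelation", {
  h <- phantom_header(n_samples = 384L, n_ascans = 48L, n_bscans = 2L,
                      n_repeats = 2L)
  sp <- phantom_spec(layers = layers3(),
                     vessel_layers = data.frame(name = "MCP", depth_um = 150,
                                                target_density_pct = 25),
                     flow_fraction = 0, noise_sigma = 3, seed = 78)
  ph <- generate_raw_spectra(sp, h)
  vol <- reconstruct_volume(ph$volume)
  sc <- bm_scan(vol$amplitude[, , 1, ], 5.03)
  d <- fsada(sc)$decorrelation
  rows <- ph$truth$vessel_rows[[1]]
  cols <- which(ph$truth$vessel_masks[[1]][1, ])
  # noise floor: static tissue voxels inside the bright layers
  tissue_rows <- round(layers3()$depth_um[1] / vol$z_spacing_um) + 3:8
  expect_lt(mean(d[rows, cols]),
            mean(d[tissue_rows, ]) + 0.05)
})

test_that("en-face vasculature fixtures hit their density targets", {
  g0 <- generate_enface_vasculature(64, 64, 1.5, target_density_pct = 0,
                                    seed = 1)
  expect_equal(sum(g0$mask$mask), 0)
  expect_equal(vessel_density(g0$mask), 0)
  g <- generate_enface_vasculature(160, 160, 1.5, target_density_pct = 25,
                                   seed = 7)
  expect_gte(vessel_density(g$mask), 23)
  expect_lte(vessel_density(g$mask), 27)
  # determinism
  g2 <- generate_enface_vasculature(160, 160, 1.5, target_density_pct = 25,
                                    seed = 7)
  expect_identical(g$image$pixels, g2$image$pixels)
  expect_identical(g$mask$mask, g2$mask$mask)
})

test_that("fixture preconditions are enforced", {
  expect_error(generate_enface_vasculature(64, 64, 1.5, 60, seed = 1),
               "\\(0, 60\\)")
  expect_error(generate_enface_vasculature(64, 64, 5, 20,
                                           caliber_range_um = c(4, 12),
                                           seed = 1),
               "below 2 px")
})

test_that("aoslo phantom cells move at the requested velocity", {
  # stationary cells: identical centroids before jitter
  v0 <- generate_aoslo_video(0, n_frames = 10, jitter_px = 0, seed = 3)
  expect_equal(diff(range(v0$track$x_px)), 0)
  # 24.4 um/s at 16.6 Hz: inter-frame displacement 24.4/16.6 ~ 1.47 um
  v1 <- generate_aoslo_video(24.4, frame_rate_hz = 16.6, n_frames = 20,
                             jitter_px = 0, seed = 3)
  step_um <- diff(v1$track$x_px) * v1$video$scale_um_per_px
  expect_equal(mean(step_um), 24.4 / 16.6, tolerance = 1e-9)
  expect_error(generate_aoslo_video(10, cell_length_um = 130,
                                    cell_spacing_um = 122),
               "exceeds")
})

test_that("velocity is recovered end-to-end from a jittered video", {
  g <- generate_aoslo_video(24.4, frame_rate_hz = 16.6, n_frames = 40,
                            jitter_px = 1, seed = 11)
  reg <- register_video(g$video, reference_index = 1L, max_shift = 6L)
  start <- c(g$track$x_px[1], g$track$y_px[1]) + g$jitter[1, 2:1]
  tr <- track_bright_cell(reg$video, start_xy = start, window_px = 17L)
  est <- estimate_velocity(tr)
  expect_lt(abs(est$velocity_um_s - 24.4) / 24.4, 0.05)
})
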