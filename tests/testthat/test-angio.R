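# BM-scan registration and FSADA: transform recovery, the decorrelation
# formula's forced values and Rayleigh limit, structural masking, and the
# flux-contrast invariants.

rayleigh_mat <- function(n, m, seed) {
  set.seed(seed)
  matrix(sqrt(rnorm(n * m)^2 + rnorm(n * m)^2) / sqrt(2), n, m)
}

test_that("identical frames register with identity transforms", {
  set.seed(5)
  f <- matrix(runif(64 * 32), 64, 32)
  reg <- register_bm_scan(bm_scan(array(c(f, f, f), c(64, 32, 3)), 5))
  expect_true(all(abs(reg$transforms$dx_px) < 0.2))
  expect_true(all(abs(reg$transforms$dz_px) < 0.2))
  expect_true(all(abs(reg$transforms$shear_v) < 0.005))
  expect_true(all(reg$transforms$ncc_after >= reg$transforms$ncc_before))
})

motion_phantom <- function(dx, dz, shear, seed = 5) {
  h <- small_header(n_samples = 384L, n_ascans = 64L, n_bscans = 1L,
                    n_repeats = 2L)
  sp <- phantom_spec(layers = layers3(), vessel_layers = no_vessels(),
                     noise_sigma = 2, seed = seed,
                     bulk_motion = data.frame(bscan = 1, repeat_idx = 2,
                                              dx_px = dx, dz_px = dz,
                                              shear_v = shear))
  ph <- generate_raw_spectra(sp, h)
  vol <- reconstruct_volume(ph$volume)
  register_bm_scan(bm_scan(vol$amplitude[, , 1, ], 5.03))
}

test_that("injected translation is recovered within half a pixel", {
  reg <- motion_phantom(3, 2, 0)
  expect_lt(abs(reg$transforms$dx_px[2] - (-3)), 0.5)
  expect_lt(abs(reg$transforms$dz_px[2] - (-2)), 0.5)
})

test_that("injected vertical shear is recovered within 0.005", {
  reg <- motion_phantom(0, 0, 0.02)
  expect_lt(abs(reg$transforms$shear_v[2] - (-0.02)), 0.005)
})

test_that("FSADA produces its forced values", {
  a <- matrix(runif(32 * 16) + 0.5, 32, 16)
  sc <- bm_scan(array(c(a, a), c(32, 16, 2)), 5)
  expect_true(all(fsada(sc)$decorrelation == 0))
  b <- a; b[5, 5] <- 0
  d <- fsada(bm_scan(array(c(a, b), c(32, 16, 2)), 5))$decorrelation
  expect_equal(d[5, 5], 1)
  # both amplitudes zero -> no evidence of flow
  a0 <- a; a0[7, 7] <- 0; b0 <- b; b0[7, 7] <- 0
  d0 <- fsada(bm_scan(array(c(a0, b0), c(32, 16, 2)), 5))$decorrelation
  expect_equal(d0[7, 7], 0)
  # log-scaled input rejected
  expect_error(fsada(bm_scan(array(c(a - 2, a - 2), c(32, 16, 2)), 5)),
               "log-scaled")
  expect_error(fsada(sc, pair_step = 2), "pair_step")
})

test_that("i.i.d. Rayleigh amplitudes give mean D = 1 - pi/4", {
  a <- rayleigh_mat(500, 200, 1)
  b <- rayleigh_mat(500, 200, 2)
  d <- fsada(bm_scan(array(c(a, b), c(500, 200, 2)), 5))
  expect_equal(mean(d$decorrelation), 1 - pi / 4, tolerance = 0.01 / 0.215)
  expect_lt(abs(mean(d$decorrelation) - (1 - pi / 4)), 0.01)
})

test_that("D is symmetric under frame order and invariant to amplitude scale", {
  a <- rayleigh_mat(64, 32, 3); b <- rayleigh_mat(64, 32, 4)
  d1 <- fsada(bm_scan(array(c(a, b), c(64, 32, 2)), 5))$decorrelation
  d2 <- fsada(bm_scan(array(c(b, a), c(64, 32, 2)), 5))$decorrelation
  expect_equal(d1, d2)
  d3 <- fsada(bm_scan(array(c(7 * a, 7 * b), c(64, 32, 2)), 5))$decorrelation
  expect_lt(max(abs(d3 - d1)), 1e-9)
})

test_that("structural masking follows the quantile semantics", {
  set.seed(6)
  a <- rayleigh_mat(48, 24, 5); b <- rayleigh_mat(48, 24, 6)
  ang <- fsada(bm_scan(array(c(a, b), c(48, 24, 2)), 5))
  s <- matrix(runif(48 * 24), 48, 24)
  m0 <- mask_structural(ang, s, 0)
  expect_identical(m0$decorrelation, ang$decorrelation)
  m1 <- mask_structural(ang, s, 1)
  expect_true(all(m1$decorrelation[s < max(s)] == 0))
})

test_that("masking suppresses noise-floor D and keeps vessel D", {
  vr <- vessel_recon()
  vol <- vr$vol
  truth <- vr$phantom$truth
  b <- 10L
  sc <- bm_scan(vol$amplitude[, , b, ], vol$repetition_time_ms)
  ang <- fsada(sc)
  struct <- apply(sc$frames, c(1, 2), mean)
  masked <- mask_structural(ang, struct, 0.5)
  # false positives: high-D pixels in the signal-free zone above the retina
  air <- 5:round(60 / vol$z_spacing_um)
  fp_before <- sum(ang$decorrelation[air, ] > 0.1)
  fp_after <- sum(masked$decorrelation[air, ] > 0.1)
  expect_lte(fp_after, 0.1 * fp_before)
  # vessel decorrelation retained
  rows <- truth$vessel_rows[[1]]
  cols <- which(truth$vessel_masks[[1]][b, ])
  kept <- mean(masked$decorrelation[rows, cols] ==
                 ang$decorrelation[rows, cols])
  expect_gte(kept, 0.95)
})

test_that("torpid vessels exceed a fixed D threshold less often than euthermic", {
  h <- phantom_header(n_samples = 384L, n_ascans = 48L, n_bscans = 6L,
                      n_repeats = 2L)
  one_plexus <- data.frame(name = "MCP", depth_um = 150,
                           target_density_pct = 25)
  frac_above <- function(flow, seed) {
    sp <- phantom_spec(layers = layers3(), vessel_layers = one_plexus,
                       flow_fraction = flow, noise_sigma = 3, seed = seed)
    ph <- generate_raw_spectra(sp, h)
    vol <- reconstruct_volume(ph$volume)
    above <- 0; tot <- 0
    for (b in 1:6) {
      d <- fsada(bm_scan(vol$amplitude[, , b, ], 5.03))$decorrelation
      rows <- ph$truth$vessel_rows[[1]]
      cols <- which(ph$truth$vessel_masks[[1]][b, ])
      above <- above + sum(d[rows, cols] > 0.3)
      tot <- tot + length(rows) * length(cols)
    }
    above / tot
  }
  expect_lt(frac_above(0.03, 91), frac_above(0.85, 92))
})

test_that("VISTA pair skipping does not decrease slow-flow decorrelation", {
  h <- phantom_header(n_samples = 384L, n_ascans = 48L, n_bscans = 4L,
                      n_repeats = 4L)
  sp <- phantom_spec(layers = layers3(),
                     vessel_layers = data.frame(name = "MCP", depth_um = 150,
                                                target_density_pct = 25),
                     flow_fraction = 0.3, noise_sigma = 3, seed = 93)
  ph <- generate_raw_spectra(sp, h)
  vol <- reconstruct_volume(ph$volume)
  mean_d <- function(p) {
    out <- numeric(0)
    for (b in 1:4) {
      sc <- bm_scan(vol$amplitude[, , b, ], 5.03)
      d <- fsada(sc, pair_step = p)
      rows <- ph$truth$vessel_rows[[1]]
      cols <- which(ph$truth$vessel_masks[[1]][b, ])
      out <- c(out, d$decorrelation[rows, cols])
    }
    mean(out)
  }
  expect_gte(mean_d(2), mean_d(1))
  # effective interscan interval book-keeping
  sc <- bm_scan(vol$amplitude[, , 1, ], 5.03)
  expect_equal(fsada(sc, 2)$effective_interval_ms, 2 * 5.03)
})
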