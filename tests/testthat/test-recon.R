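# Spectral-domain reconstruction: k-space resampling, DC removal,
# dispersion compensation and estimation, Fourier reconstruction, and the
# closed-form optics calculators.

k_linear_calibration <- function(n, lambda_min = 750, lambda_max = 930) {
  # per-pixel wavelengths sampled uniformly (and increasing) in k, so the
  # resampling grid coincides with the native sampling
  k <- seq(2 * pi / (lambda_max / 1e3), 2 * pi / (lambda_min / 1e3),
           length.out = n)
  2 * pi / k * 1e3   # nm, decreasing in p; k increasing in p
}

test_that("resampling is the identity on an already k-linear grid", {
  n <- 128L
  lam <- k_linear_calibration(n)   # per-pixel calibration, linear in k
  set.seed(1)
  fr <- matrix(rnorm(n * 4), n, 4)
  out <- resample_to_k(fr, lam)
  expect_lt(max(abs(out - fr)) / max(abs(fr)), 1e-9)
})

test_that("constant spectra stay constant and bad calibrations error", {
  fr <- matrix(5, 64, 3)
  out <- resample_to_k(fr, c(750, 180 / 63))
  expect_lt(max(abs(out - 5)), 1e-9)
  expect_error(resample_to_k(fr, c(750, 0)), "monotonic")
})

test_that("k-space resampling sharpens deep fringes on a lambda-linear grid", {
  n <- 512L
  cal <- c(750, 180 / (n - 1))     # linear in lambda, curved in k
  lam <- 750 + 180 * (0:(n - 1)) / (n - 1)
  k <- 2 * pi / (lam / 1e3)
  dk <- (max(k) - min(k)) / (n - 1)
  z <- 0.8 * pi / (2 * dk)         # 80% of the depth range
  fr <- matrix(cos(2 * k * z), n, 2)
  fwhm_bins <- function(amp) {
    a <- amp[, 1]; pk <- which.max(a)
    sum(a > max(a) / 2)
  }
  raw_amp <- reconstruct_frame(fr, k_grid = seq(min(k), max(k),
                                                length.out = n))
  res <- resample_to_k(fr, cal)
  res_amp <- reconstruct_frame(res)
  expect_lt(fwhm_bins(res_amp), 0.8 * fwhm_bins(raw_amp))
})

test_that("DC/autocorrelation removal zeroes per-sample means exactly", {
  set.seed(2)
  fr <- matrix(rnorm(64 * 8, mean = 100), 64, 8)
  fr[, 3] <- fr[, 3] + 50          # outlier A-scan
  out <- remove_dc_autocorrelation(fr)
  expect_lt(max(abs(rowMeans(out))), 1e-9 * max(abs(fr)))
  # identical A-scans cancel entirely
  same <- matrix(rep(rnorm(64), 5), 64, 5)
  expect_lt(max(abs(remove_dc_autocorrelation(same))), 1e-12)
  expect_error(remove_dc_autocorrelation(matrix(1, 64, 1)), "2 A-scans")
})

test_that("DC removal preserves the fringe component of phantom frames", {
  h <- small_header(n_samples = 256L, n_ascans = 32L, n_bscans = 1L)
  raw <- phantom_single_reflector(h, z_um = 150, noise_sigma = 0, seed = 3)
  fr <- get_frame(raw, 1, 1)
  lam <- header_wavelengths(h)
  env <- 1500 * exp(-(lam - 850)^2 / (2 * (165 / 2.355)^2))
  out <- remove_dc_autocorrelation(fr)
  expect_gt(cor(as.vector(out), as.vector(fr - env)), 0.99)
})

test_that("zero dispersion coefficients leave the reconstruction unchanged", {
  lr <- layered_recon()
  fr <- remove_dc_autocorrelation(resample_to_k(
    get_frame(lr$phantom$volume, 1, 1), lr$header$wavelength_calibration))
  a0 <- reconstruct_frame(fr)
  a1 <- reconstruct_frame(apply_dispersion(fr, dispersion_coefficients(0, 0)))
  expect_lt(max(abs(a1 - a0)) / max(a0), 1e-9)
})

test_that("reconstruction amplitude is invariant to a global phasor phase", {
  lr <- layered_recon()
  fr <- remove_dc_autocorrelation(resample_to_k(
    get_frame(lr$phantom$volume, 1, 1), lr$header$wavelength_calibration))
  z <- apply_dispersion(fr, dispersion_coefficients(25, 10))
  a1 <- reconstruct_frame(z)
  a2 <- reconstruct_frame(z * exp(1i * 1.234))
  expect_lt(max(abs(a2 - a1)) / max(a1), 1e-6)
})

disp_frame <- function(a2, seed = 31, z_um = 200) {
  h <- small_header(n_samples = 384L, n_ascans = 48L, n_bscans = 1L)
  raw <- phantom_single_reflector(h, z_um = z_um, dispersion = c(a2, 0),
                                  noise_sigma = 1, seed = seed)
  remove_dc_autocorrelation(resample_to_k(get_frame(raw, 1, 1),
                                          h$wavelength_calibration))
}

peak_fwhm <- function(amp) {
  a <- rowMeans(amp)
  sum(a > max(a) / 2)
}

test_that("compensating injected dispersion restores the sharp peak", {
  ref <- peak_fwhm(reconstruct_frame(disp_frame(0)))
  fr <- disp_frame(40)
  broad <- peak_fwhm(reconstruct_frame(apply_dispersion(
    fr, dispersion_coefficients(0, 0))))
  comp <- peak_fwhm(reconstruct_frame(apply_dispersion(
    fr, dispersion_coefficients(40, 0))))
  wrong <- peak_fwhm(reconstruct_frame(apply_dispersion(
    fr, dispersion_coefficients(-40, 0))))
  expect_gt(broad, 2 * ref)             # injected dispersion broadens
  expect_lte(comp, ceiling(1.1 * ref))  # matched coefficients restore
  expect_gt(wrong, comp)                # sign matters
})

test_that("all-zero spectra reconstruct to zero and Parseval holds", {
  z <- reconstruct_frame(matrix(0, 64, 3),
                         k_grid = seq(7, 8, length.out = 64))
  expect_true(all(z == 0))
  # band-limited zero-mean real frame: energy splits half into the
  # positive-frequency amplitudes
  n <- 256L
  set.seed(4)
  t <- seq_len(n) - 1
  x <- matrix(0, n, 2)
  for (j in 1:2) {
    bins <- sample(5:(n / 2 - 5), 20)       # integer frequencies: no DC,
    amps <- runif(20); phis <- runif(20, 0, 2 * pi)  # no Nyquist energy
    for (i in seq_len(20))
      x[, j] <- x[, j] + amps[i] * cos(2 * pi * bins[i] * t / n + phis[i])
  }
  amp <- reconstruct_frame(x, k_grid = seq(7, 8, length.out = n))
  expect_equal(sum(amp^2), 0.5 * sum(x^2), tolerance = 1e-6)
})

test_that("a pure cosine fringe lands on its closed-form depth bin", {
  n <- 256L
  k <- seq(7.0, 8.6, length.out = n)
  dk <- k[2] - k[1]
  for (m in c(20L, 77L, 120L)) {
    z <- m * pi / (n * dk)
    fr <- matrix(cos(2 * k * z), n, 1)
    fr <- fr - mean(fr)
    amp <- reconstruct_frame(fr, k_grid = k)
    expect_equal(which.max(amp[, 1]) - 1L, m)
  }
})

test_that("dispersion estimation recovers injected coefficients", {
  est <- estimate_dispersion(disp_frame(40))
  expect_lt(abs(est$a2 - 40), 4)        # within 10% of a2*
  # null case: well below 5% of the search bounds
  est0 <- estimate_dispersion(disp_frame(0))
  expect_lt(abs(est0$a2), 10)
  expect_lt(abs(est0$a3), 25)
})

test_that("estimated coefficients are no worse than the truth (entropy)", {
  fr <- disp_frame(40)
  est <- estimate_dispersion(fr)
  cost_est <- sdocta:::dispersion_cost(fr, est)
  cost_truth <- sdocta:::dispersion_cost(
    fr, dispersion_coefficients(40, 0, est$k0))
  cost_zero <- sdocta:::dispersion_cost(
    fr, dispersion_coefficients(0, 0, est$k0))
  expect_lte(cost_est, cost_truth + 1e-6)
  expect_lte(cost_est, cost_zero)
})

test_that("re-estimating on a compensated frame returns near-zero", {
  fr <- disp_frame(40)
  est <- estimate_dispersion(fr)
  comp <- apply_dispersion(fr, est)
  # build a real compensated frame for re-estimation
  re <- Re(comp)
  attr(re, "k_grid") <- attr(comp, "k_grid")
  est2 <- estimate_dispersion(re)
  expect_lt(abs(est2$a2), 0.1 * max(abs(est$a2), 10))
})

test_that("spectrometer depth range reproduces the printed 2.0 mm", {
  sp <- spectrometer_spec(750, 930, 2048)
  expect_equal(round(max_depth_range(sp, 840), 1), 2.0)
  # doubling the pixel count doubles the range
  sp2 <- spectrometer_spec(750, 930, 4096)
  expect_equal(max_depth_range(sp2, 840), 2 * max_depth_range(sp, 840))
  # closed-form arithmetic case
  sp3 <- spectrometer_spec(799.9, 800.1, 2)   # delta_lambda = 0.1 nm
  expect_equal(round(max_depth_range(sp3, 800), 1), 1.6)
})

test_that("theoretical axial resolution matches both printed sources", {
  expect_equal(round(axial_resolution_theoretical(source_spec(850, 165)), 1),
               1.5)
  expect_equal(round(axial_resolution_theoretical(
    source_spec(878.4, 186.3)), 1), 1.4)
  s <- source_spec(850, 82.5)
  expect_equal(axial_resolution_theoretical(s),
               2 * axial_resolution_theoretical(source_spec(850, 165)))
})

test_that("the full chain recovers layer depths and reflectivity order", {
  lr <- layered_recon()
  amp <- apply(lr$vol$amplitude, c(1, 2, 3), mean)
  prof <- rowMeans(amp)
  dz <- lr$vol$z_spacing_um
  peaks <- numeric(3)
  for (i in 1:3) {
    band <- round(layers3()$depth_um[i] / dz) + (-8:12)
    peaks[i] <- band[which.max(prof[band])]
  }
  tops <- round(layers3()$depth_um / dz) + 1
  expect_true(all(abs(peaks - tops) <= layers3()$thickness_um / dz + 1))
  # layer-mean amplitudes rank like the injected reflectivities (L3 > L1 > L2)
  layer_mean <- vapply(1:3, function(i) {
    zi <- which((seq_len(nrow(amp)) - 1) * dz >= layers3()$depth_um[i] &
                (seq_len(nrow(amp)) - 1) * dz <
                  layers3()$depth_um[i] + layers3()$thickness_um[i])
    mean(prof[zi])
  }, 0)
  expect_identical(order(layer_mean, decreasing = TRUE), c(3L, 1L, 2L))
})
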