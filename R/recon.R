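# Spectral-domain OCT reconstruction: resampling of raw spectra to a uniform
# wavenumber grid, DC/autocorrelation mitigation, dispersion compensation by
# phasor multiplication (coefficients estimated by entropy minimization), and
# Fourier transformation to depth. Closed-form spectrometer/source optics
# calculators live here too.
#
# Conventions: a "frame" is a numeric matrix with spectral samples in rows
# and A-scans in columns. Wavenumber k = 2*pi/lambda is in rad/um; depths in
# um. A frame resampled by resample_to_k() carries its k grid in attribute
# "k_grid"; depth spacing of a reconstructed frame is pi/(N * dk).

#' Light-source specification
#'
#' @param center_wavelength_nm center wavelength lambda_0 (nm).
#' @param bandwidth_nm FWHM bandwidth (nm).
#' @param tissue_group_index group refractive index of tissue (default 1.33).
#' @return object of class `source_spec`.
#' @export
source_spec <- function(center_wavelength_nm = 850,
                        bandwidth_nm = 165,
                        tissue_group_index = 1.33) {
  if (!(center_wavelength_nm > bandwidth_nm && bandwidth_nm > 0))
    stop("source_spec: need lambda_0 > delta_lambda > 0")
  if (tissue_group_index < 1) stop("source_spec: group index must be >= 1")
  structure(list(center_wavelength_nm = center_wavelength_nm,
                 bandwidth_nm = bandwidth_nm,
                 tissue_group_index = tissue_group_index),
            class = "source_spec")
}

#' Spectrometer specification
#'
#' @param lambda_min_nm,lambda_max_nm wavelength range covered by the camera.
#' @param n_pixels camera pixels.
#' @return object of class `spectrometer_spec` with derived per-pixel
#'   wavelength spacing `delta_lambda_nm`.
#' @export
spectrometer_spec <- function(lambda_min_nm = 750, lambda_max_nm = 930,
                              n_pixels = 2048L) {
  if (!(lambda_max_nm > lambda_min_nm)) stop("spectrometer_spec: max <= min")
  if (n_pixels < 2L) stop("spectrometer_spec: n_pixels must be >= 2")
  structure(list(lambda_min_nm = lambda_min_nm, lambda_max_nm = lambda_max_nm,
                 n_pixels = as.integer(n_pixels),
                 delta_lambda_nm = (lambda_max_nm - lambda_min_nm) / n_pixels),
            class = "spectrometer_spec")
}

#' Dispersion compensation coefficients
#'
#' Phase of the compensating phasor: `a2*(k - k0)^2 + a3*(k - k0)^3`, k in
#' rad/um.
#'
#' @param a2 second-order coefficient (rad um^2).
#' @param a3 third-order coefficient (rad um^3).
#' @param k0 center wavenumber (rad/um); defaults to 2*pi/0.850.
#' @export
dispersion_coefficients <- function(a2 = 0, a3 = 0, k0 = 2 * pi / 0.850) {
  if (!all(is.finite(c(a2, a3, k0)))) stop("dispersion: coefficients not finite")
  if (k0 <= 0) stop("dispersion: k0 must be positive")
  structure(list(a2 = a2, a3 = a3, k0 = k0),
            class = "dispersion_coefficients")
}

#' Maximum imaging depth range of a spectrometer
#'
#' `z_max = lambda_0^2 / (4 * delta_lambda)` in air, where `delta_lambda` is
#' the per-pixel wavelength spacing of the spectrometer.
#'
#' @param spec a [spectrometer_spec()].
#' @param center_lambda_nm center wavelength (nm); default: midpoint of the
#'   spectrometer range.
#' @return depth range in millimetres.
#' @export
max_depth_range <- function(spec, center_lambda_nm = NULL) {
  if (spec$delta_lambda_nm <= 0) stop("max_depth_range: delta_lambda <= 0")
  lam0 <- center_lambda_nm %||%
    ((spec$lambda_min_nm + spec$lambda_max_nm) / 2)
  lam0^2 / (4 * spec$delta_lambda_nm) / 1e6  # nm -> mm
}

#' Theoretical axial resolution of a Gaussian source
#'
#' `(2 ln 2 / pi) * lambda_0^2 / delta_lambda`, divided by the tissue group
#' index when `in_tissue`.
#'
#' @param src a [source_spec()].
#' @param in_tissue report resolution in tissue (default) or in air.
#' @return axial resolution in micrometres.
#' @export
axial_resolution_theoretical <- function(src, in_tissue = TRUE) {
  r_nm <- (2 * log(2) / pi) * src$center_wavelength_nm^2 / src$bandwidth_nm
  if (in_tissue) r_nm <- r_nm / src$tissue_group_index
  r_nm / 1e3  # nm -> um
}

uniform_k_grid <- function(lambda_nm) {
  k <- 2 * pi / (lambda_nm / 1e3)   # rad/um
  seq(min(k), max(k), length.out = length(k))
}

#' Resample a raw frame onto a uniform wavenumber grid
#'
#' Each A-scan (column) is cubic-spline interpolated from the spectrometer's
#' native wavelength sampling onto a uniform grid in `k = 2*pi/lambda`
#' spanning `[2*pi/lambda_max, 2*pi/lambda_min]`. Queries outside the native
#' support (there are none when the grids share endpoints, but guard anyway)
#' are clamped to the endpoint values rather than extrapolated.
#'
#' @param frame numeric matrix, spectral samples in rows, A-scans in columns.
#' @param calibration polynomial coefficients mapping 0-based pixel index to
#'   wavelength in nm (as in [raw_scan_header()]), or a full per-pixel
#'   wavelength vector of length `nrow(frame)`.
#' @return matrix of the same shape with attribute `k_grid` (rad/um).
#' @export
resample_to_k <- function(frame, calibration) {
  n <- nrow(frame)
  if (length(calibration) == n && n > 8L) {
    lam <- calibration
  } else {
    p <- seq_len(n) - 1
    lam <- numeric(n)
    for (j in seq_along(calibration)) lam <- lam + calibration[j] * p^(j - 1)
  }
  d <- diff(lam)
  if (!(all(d > 0) || all(d < 0)))
    stop("resample_to_k: calibration is not strictly monotonic")
  k_native <- 2 * pi / (lam / 1e3)
  ord <- order(k_native)
  kx <- k_native[ord]
  # canonical ascending-k output grid (columns are reversed relative to the
  # pixel axis when the camera samples descending k)
  grid <- seq(kx[1L], kx[n], length.out = n)
  out <- matrix(0, n, ncol(frame))
  gq <- pmin(pmax(grid, kx[1L]), kx[n])
  for (j in seq_len(ncol(frame))) {
    sf <- stats::splinefun(kx, frame[ord, j], method = "natural")
    out[, j] <- sf(gq)
  }
  attr(out, "k_grid") <- grid
  out
}

#' Remove DC term and autocorrelation background from a frame
#'
#' Subtracts the mean spectrum across A-scans (line scans) of the frame from
#' every A-scan, so each spectral sample has exactly zero mean over the
#' frame. Requires at least two A-scans (with a single A-scan the subtraction
#' would null the signal itself).
#'
#' @param frame matrix, spectral samples in rows, A-scans in columns.
#' @return zero-mean frame; the `k_grid` attribute, if present, is kept.
#' @export
remove_dc_autocorrelation <- function(frame) {
  if (ncol(frame) < 2L)
    stop("remove_dc_autocorrelation: frame must contain >= 2 A-scans")
  out <- frame - rowMeans(frame)
  attr(out, "k_grid") <- attr(frame, "k_grid")
  out
}

analytic_signal <- function(frame) {
  # zero the negative-frequency half of each column's spectrum (rows are the
  # "time"-like k axis). DC (bin 1) and Nyquist (bin N/2+1 for even N) kept,
  # positive bins kept unscaled so the positive-frequency modulus matches the
  # real-signal reconstruction exactly.
  n <- nrow(frame)
  x <- stats::mvfft(frame)
  neg <- if (n %% 2L == 0L) seq.int(n / 2L + 2L, n) else
    seq.int((n + 1L) / 2L + 1L, n)
  x[neg, ] <- 0
  stats::mvfft(x, inverse = TRUE) / n
}

#' Apply dispersion compensation to a frame
#'
#' Builds the analytic signal of each A-scan (negative spectral frequencies
#' zeroed) and multiplies it by the phasor
#' `exp(-i * (a2*(k-k0)^2 + a3*(k-k0)^3))`. With `a2 = a3 = 0` the modulus of
#' the subsequent Fourier reconstruction is unchanged.
#'
#' @param frame zero-mean k-uniform frame from [remove_dc_autocorrelation()]
#'   (must carry a `k_grid` attribute or be given `k_grid`).
#' @param coeffs a [dispersion_coefficients()].
#' @param k_grid optional explicit wavenumber grid (rad/um).
#' @return complex matrix with attribute `k_grid`.
#' @export
apply_dispersion <- function(frame, coeffs, k_grid = NULL) {
  k <- k_grid %||% attr(frame, "k_grid")
  if (is.null(k)) stop("apply_dispersion: no k_grid available")
  z <- analytic_signal(frame)
  dk <- k - coeffs$k0
  phasor <- exp(-1i * (coeffs$a2 * dk^2 + coeffs$a3 * dk^3))
  out <- z * phasor
  attr(out, "k_grid") <- k
  out
}

#' Fourier reconstruction of one frame
#'
#' Per A-scan, the modulus of the positive-frequency half of the Fourier
#' transform over k, scaled by `1/sqrt(N)` so that for a real zero-mean frame
#' the summed squared amplitude equals half the summed squared spectral
#' samples (Parseval). The depth axis has `N/2` pixels with spacing
#' `pi/(N*dk)` um.
#'
#' @param frame real or complex k-uniform frame (zero-mean).
#' @param k_grid optional explicit wavenumber grid.
#' @return non-negative matrix `N/2 x n_ascans` with attribute
#'   `z_spacing_um` (NA when no k grid is known).
#' @export
reconstruct_frame <- function(frame, k_grid = NULL) {
  n <- nrow(frame)
  k <- k_grid %||% attr(frame, "k_grid")
  amp <- Mod(stats::mvfft(frame))[seq_len(n %/% 2L), , drop = FALSE] / sqrt(n)
  attr(amp, "z_spacing_um") <- if (is.null(k)) NA_real_ else
    pi / (n * abs(k[2L] - k[1L]))
  amp
}

#' Log-scale an amplitude image for display
#'
#' `20*log10(amplitude + eps)` with `eps = 1e-12 * max(amplitude)`; display
#' only — angiography always consumes linear amplitudes.
#'
#' @param amplitude non-negative matrix or array.
#' @export
log_display <- function(amplitude) {
  eps <- 1e-12 * max(amplitude, 1e-300)
  20 * log10(amplitude + eps)
}

shannon_entropy <- function(intensity) {
  s <- sum(intensity)
  if (s <= 0) return(0)
  p <- intensity / s
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Sharpness cost of a reconstructed frame
#'
#' Shannon entropy of the normalized intensity (squared amplitude) image;
#' lower is sharper. Used as the objective of [estimate_dispersion()].
#'
#' @param frame zero-mean k-uniform frame.
#' @param coeffs trial [dispersion_coefficients()].
#' @keywords internal
dispersion_cost <- function(frame, coeffs) {
  amp <- reconstruct_frame(apply_dispersion(frame, coeffs))
  shannon_entropy(amp^2)
}

#' Estimate dispersion coefficients by entropy minimization
#'
#' Searches `(a2, a3)` minimizing the Shannon entropy of the reconstructed
#' intensity image with a multi-start Nelder-Mead simplex, bounds enforced by
#' clamping with a quadratic penalty. The returned cost never exceeds the
#' cost of the uncompensated `(0, 0)` reconstruction.
#'
#' @param frame zero-mean k-uniform frame containing at least one bright
#'   reflector.
#' @param k0 center wavenumber (rad/um); default: grid midpoint.
#' @param bounds search bounds `c(a2_max, a3_max)` (rad um^2, rad um^3).
#' @param starts list of starting points `c(a2, a3)`.
#' @param maxit iteration budget per start.
#' @return a [dispersion_coefficients()] with attributes `cost` and
#'   `converged` (FALSE when the iteration budget was exhausted; the
#'   best-so-far estimate is still returned).
#' @export
estimate_dispersion <- function(frame, k0 = NULL, bounds = c(200, 500),
                                starts = list(c(0, 0), c(60, 0), c(-60, 0)),
                                maxit = 300L) {
  k <- attr(frame, "k_grid")
  if (is.null(k)) stop("estimate_dispersion: frame has no k_grid")
  k0 <- k0 %||% ((min(k) + max(k)) / 2)
  fn <- function(par) {
    pen <- sum(pmax(abs(par) - bounds, 0)^2)
    par <- pmin(pmax(par, -bounds), bounds)
    dispersion_cost(frame, dispersion_coefficients(par[1L], par[2L], k0)) +
      pen
  }
  best <- list(par = c(0, 0), value = fn(c(0, 0)), converged = TRUE)
  for (s in starts) {
    o <- stats::optim(s, fn, method = "Nelder-Mead",
                      control = list(maxit = maxit,
                                     reltol = 1e-10))
    if (o$value < best$value)
      best <- list(par = o$par, value = o$value,
                   converged = o$convergence == 0L)
  }
  par <- pmin(pmax(best$par, -bounds), bounds)
  out <- dispersion_coefficients(par[1L], par[2L], k0)
  attr(out, "cost") <- best$value
  attr(out, "converged") <- best$converged
  if (!best$converged)
    warning("estimate_dispersion: iteration budget exhausted; ",
            "returning best coefficients found")
  out
}

#' Structural volume
#'
#' Reconstructed linear amplitudes indexed `[depth, A-scan, B-scan, repeat]`
#' with axial pixel spacing in micrometres.
#'
#' @param amplitude 4-D (or 3-D, promoted) non-negative array.
#' @param z_spacing_um axial micrometres per depth pixel.
#' @param repetition_time_ms interscan interval of the source scan.
#' @param log_display whether the amplitudes have been log-scaled (display
#'   only; must be FALSE for angiography).
#' @export
structural_volume <- function(amplitude, z_spacing_um,
                              repetition_time_ms = NA_real_,
                              log_display = FALSE) {
  if (length(dim(amplitude)) == 3L)
    dim(amplitude) <- c(dim(amplitude), 1L)
  stopifnot(length(dim(amplitude)) == 4L)
  if (!log_display && any(amplitude < 0))
    stop("structural_volume: linear amplitude must be non-negative")
  structure(list(amplitude = amplitude, z_spacing_um = z_spacing_um,
                 repetition_time_ms = repetition_time_ms,
                 log_display = log_display),
            class = "structural_volume")
}

#' @export
print.structural_volume <- function(x, ...) {
  d <- dim(x$amplitude)
  cat(sprintf(paste0("structural_volume: %d depth px x %d A-scans x ",
                     "%d B-scans x %d repeats (%.3f um/px axial)\n"),
              d[1L], d[2L], d[3L], d[4L], x$z_spacing_um))
  invisible(x)
}

#' Reconstruct a full raw volume
#'
#' Runs the chain k-space resampling -> DC/autocorrelation removal ->
#' dispersion compensation -> Fourier reconstruction for every frame of a
#' raw volume.
#'
#' @param raw a [raw_spectra_volume()].
#' @param coeffs [dispersion_coefficients()] to apply; `NULL` for none.
#' @param estimate_dispersion estimate coefficients from the first frame and
#'   apply them to all frames.
#' @return a [structural_volume()] with attribute `dispersion` (the
#'   coefficients used).
#' @export
reconstruct_volume <- function(raw, coeffs = NULL,
                               estimate_dispersion = FALSE) {
  h <- raw$header
  n <- h$n_spectral_samples
  cal <- h$wavelength_calibration
  first <- remove_dc_autocorrelation(
    resample_to_k(get_frame(raw, 1L, max(1L, h$n_bscans %/% 2L)), cal))
  if (estimate_dispersion) {
    coeffs <- sdocta::estimate_dispersion(first)
  } else if (is.null(coeffs)) {
    coeffs <- dispersion_coefficients(0, 0,
                                      mean(range(attr(first, "k_grid"))))
  }
  amp <- array(0, dim = c(n %/% 2L, h$n_ascans_per_bscan, h$n_bscans,
                          h$n_repeats))
  zsp <- NA_real_
  for (b in seq_len(h$n_bscans)) {
    for (r in seq_len(h$n_repeats)) {
      fr <- resample_to_k(get_frame(raw, r, b), cal)
      fr <- remove_dc_autocorrelation(fr)
      fr <- apply_dispersion(fr, coeffs)
      a <- reconstruct_frame(fr)
      zsp <- attr(a, "z_spacing_um")
      amp[, , b, r] <- a
    }
  }
  out <- structural_volume(amp, zsp, h$repetition_time_ms)
  attr(out, "dispersion") <- coeffs
  out
}
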