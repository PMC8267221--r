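# Digital retina phantom: raw spectral interferograms from a layered,
# speckle-filled retina with per-plexus vessel trees and a tunable blood-cell
# flux model, plus injected dispersion, wavelength-grid nonlinearity, bulk
# frame motion and additive noise. The forward model per camera pixel p is
#
#   I(p) = S(lambda_p) * [1 + Re( exp(i*phi_d(k_p)) * sum_j rho_j
#                                  exp(2 i k_p z_j) )] + noise,
#
# with complex circular-Gaussian voxel reflectivities rho_j (fully developed
# speckle), dispersion phase phi_d(k) = a2 (k-k0)^2 + a3 (k-k0)^3, and k_p
# following the (possibly nonlinear) spectrometer wavelength calibration.
# "Flow" re-draws rho in vessel voxels between repeats with a Bernoulli gate
# of probability flow_fraction per interscan interval: 0 = frozen (torpid
# limit), 1 = fully decorrelating (euthermic limit).

#' Default structural layer stack of the phantom retina
#'
#' Depths are the top of each band in micrometres (optical, in air);
#' reflectivities are relative weights in `[0, 1]`.
#' @return data.frame with columns `name`, `depth_um`, `thickness_um`,
#'   `reflectivity`.
#' @export
phantom_layers <- function() {
  data.frame(name = c("NFL", "GCL_IPL", "INL", "OPL", "ONL", "PR_RPE"),
             depth_um = c(120, 145, 205, 250, 280, 350),
             thickness_um = c(25, 60, 45, 30, 70, 40),
             reflectivity = c(0.80, 0.45, 0.25, 0.50, 0.12, 0.90))
}

#' Default vessel plexus layout of the phantom retina
#'
#' Three capillary plexuses (superior, middle, deep) at inner-retinal depths
#' with densities typical of en-face OCT-A in small animals. Capillary
#' calibers default to 4-12 um (no species value is established for the
#' 13-lined ground squirrel; the mouse minimum is about 3.2 um).
#' @return data.frame with columns `name`, `depth_um`, `target_density_pct`.
#' @export
phantom_vessel_layers <- function() {
  data.frame(name = c("SCP", "MCP", "DCP"),
             depth_um = c(150, 215, 265),
             target_density_pct = c(18, 22, 18))
}

#' Phantom generative specification
#'
#' @param layers structural layer stack (see [phantom_layers()]).
#' @param vessel_layers vessel plexus table (see [phantom_vessel_layers()]).
#' @param flow_fraction probability per interscan interval that a vessel
#'   voxel's scatterers decorrelate: 0 = frozen/torpid, 1 = fully
#'   decorrelating/euthermic.
#' @param vessel_reflectivity relative reflectivity of blood in vessels.
#' @param dispersion_inject injected dispersion `c(a2, a3)` (rad um^2,
#'   rad um^3) applied to all fringes.
#' @param noise_sigma additive Gaussian camera noise (counts).
#' @param caliber_range_um vessel diameter range (um).
#' @param scale_um_per_px lateral scale of the scan grid (um/px).
#' @param envelope_peak_counts peak of the Gaussian source envelope (counts).
#' @param modulation_rms RMS fringe modulation relative to the envelope.
#' @param bulk_motion optional per-frame motion: data.frame with columns
#'   `bscan`, `repeat_idx`, `dx_px`, `dz_px`, `shear_v`.
#' @param seed RNG seed; all randomness in [generate_raw_spectra()] derives
#'   from it.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(layers = phantom_layers(),
                         vessel_layers = phantom_vessel_layers(),
                         flow_fraction = 0.9,
                         vessel_reflectivity = 0.55,
                         dispersion_inject = c(0, 0),
                         noise_sigma = 4,
                         caliber_range_um = c(4, 12),
                         scale_um_per_px = 1.5,
                         envelope_peak_counts = 1500,
                         modulation_rms = 0.12,
                         bulk_motion = NULL,
                         seed = 1L) {
  if (flow_fraction < 0 || flow_fraction > 1)
    stop("phantom_spec: flow_fraction must be in [0, 1]")
  if (nrow(layers) && (any(layers$reflectivity < 0) ||
                       any(layers$reflectivity > 1)))
    stop("phantom_spec: reflectivities must be in [0, 1]")
  structure(list(layers = layers, vessel_layers = vessel_layers,
                 flow_fraction = flow_fraction,
                 vessel_reflectivity = vessel_reflectivity,
                 dispersion_inject = dispersion_inject,
                 noise_sigma = noise_sigma,
                 caliber_range_um = caliber_range_um,
                 scale_um_per_px = scale_um_per_px,
                 envelope_peak_counts = envelope_peak_counts,
                 modulation_rms = modulation_rms,
                 bulk_motion = bulk_motion,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Default scan header for the phantom
#'
#' 130 kHz-class line rate (129.5 kHz as used on the high-speed system),
#' T_R = 5.03 ms, 750-930 nm spectrometer with a mild quadratic wavelength
#' nonlinearity, scan angle chosen so the lateral scale is
#' `scale_um_per_px` at a retinal magnification factor of 100 um/degree.
#'
#' @param n_samples,n_ascans,n_bscans,n_repeats grid sizes.
#' @param scale_um_per_px lateral scale (um/px).
#' @param rmf_um_per_deg retinal magnification factor.
#' @param lambda_nonlin_nm peak deviation (nm) of the pixel-to-wavelength map
#'   from linearity (0 gives a linear-in-lambda grid).
#' @param repetition_time_ms interscan interval T_R.
#' @param line_rate_hz A-scan rate.
#' @return a [raw_scan_header()].
#' @export
phantom_header <- function(n_samples = 512L, n_ascans = 96L, n_bscans = 96L,
                           n_repeats = 4L, scale_um_per_px = 1.5,
                           rmf_um_per_deg = 100,
                           lambda_nonlin_nm = 3,
                           repetition_time_ms = 5.03,
                           line_rate_hz = 129500) {
  g <- lambda_nonlin_nm
  np <- n_samples - 1
  cal <- c(750, (180 + 4 * g) / np, -4 * g / np^2)
  raw_scan_header(
    n_spectral_samples = n_samples,
    n_ascans_per_bscan = n_ascans,
    n_bscans = n_bscans,
    n_repeats = n_repeats,
    line_rate_hz = line_rate_hz,
    repetition_time_ms = repetition_time_ms,
    scan_angle_deg = n_ascans * scale_um_per_px / rmf_um_per_deg,
    wavelength_calibration = cal,
    bit_depth = 12L)
}

phantom_axial_grid <- function(header) {
  lam <- header_wavelengths(header)
  k <- 2 * pi / (lam / 1e3)
  n <- header$n_spectral_samples
  dk <- (max(k) - min(k)) / (n - 1)
  dz <- pi / (n * dk)
  list(k = k, dz_um = dz, z_max_um = dz * (n %/% 2L),
       z_um = (seq_len(n %/% 2L) - 1) * dz)
}

#' Generate a raw spectral volume from a phantom specification
#'
#' Runs the forward interferogram model for every frame of the scan grid and
#' returns the raw volume together with the ground truth every downstream
#' test asserts against.
#'
#' @param spec a [phantom_spec()].
#' @param header a [raw_scan_header()] describing the scan grid.
#' @return list with `volume` (a [raw_spectra_volume()]) and `truth` (class
#'   `phantom_truth`: `surface_depths_um` named per-layer matrices,
#'   `vessel_masks` named per-plexus logical en-face matrices
#'   `[n_bscans x n_ascans]`, `vessel_rows` axial pixel bands per plexus,
#'   `z_spacing_um`, `transforms` injected per-frame motion, `flow_fraction`).
#' @export
generate_raw_spectra <- function(spec, header) {
  set.seed(spec$seed)
  ax <- phantom_axial_grid(header)
  n <- header$n_spectral_samples
  nx <- header$n_ascans_per_bscan
  nb <- header$n_bscans
  nrep <- header$n_repeats
  nz <- n %/% 2L
  layers <- spec$layers
  if (nrow(layers) &&
      any(layers$depth_um + layers$thickness_um > 0.98 * ax$z_max_um))
    stop(sprintf(paste0("phantom: layer deeper than the spectrometer depth ",
                        "range (%.0f um)"), ax$z_max_um))
  if (nrow(spec$vessel_layers) &&
      any(spec$vessel_layers$depth_um > 0.98 * ax$z_max_um))
    stop("phantom: vessel layer deeper than the spectrometer depth range")

  # axial reflectivity profile of the structural layers
  r_z <- numeric(nz)
  if (nrow(layers)) {
    for (i in seq_len(nrow(layers))) {
      zi <- which(ax$z_um >= layers$depth_um[i] &
                  ax$z_um < layers$depth_um[i] + layers$thickness_um[i])
      r_z[zi] <- pmax(r_z[zi], layers$reflectivity[i])
    }
  }

  # vessel plexus masks on the en-face grid and their axial pixel bands
  vl <- spec$vessel_layers
  vessel_masks <- list()
  vessel_rows <- list()
  if (!is.null(vl) && nrow(vl)) {
    for (i in seq_len(nrow(vl))) {
      vessel_masks[[vl$name[i]]] <-
        generate_vessel_tree_mask(nb, nx, spec$scale_um_per_px,
                                  vl$target_density_pct[i],
                                  spec$caliber_range_um)
      c0 <- round(vl$depth_um[i] / ax$dz_um) + 1L
      vessel_rows[[vl$name[i]]] <-
        pmax(2L, pmin(nz, (c0 - 1L):(c0 + 1L)))
    }
  }
  vrows_all <- sort(unique(unlist(vessel_rows)))

  lam <- header_wavelengths(header)
  env <- spec$envelope_peak_counts *
    exp(-(lam - 850)^2 / (2 * (165 / 2.355)^2))
  k <- ax$k
  k0 <- mean(range(k))
  phi_d <- spec$dispersion_inject[1L] * (k - k0)^2 +
    spec$dispersion_inject[2L] * (k - k0)^3
  disp_phasor <- exp(1i * phi_d)
  fringe_mat <- exp(2i * outer(k, ax$z_um))        # n x nz

  # normalization: RMS fringe modulation relative to the envelope
  mean_r2 <- sum(r_z^2) +
    if (length(vessel_rows))
      sum(vapply(seq_along(vessel_rows), function(i) {
        mean(vessel_masks[[i]]) * length(vessel_rows[[i]]) *
          max(0, spec$vessel_reflectivity^2 -
                mean(r_z[vessel_rows[[i]]]^2))
      }, 0))
    else 0
  alpha <- spec$modulation_rms / sqrt(0.5 * max(mean_r2, 1e-12))

  motion <- spec$bulk_motion
  get_motion <- function(b, r) {
    if (is.null(motion)) return(c(0, 0, 0))
    row <- motion[motion$bscan == b & motion$repeat_idx == r, , drop = FALSE]
    if (!nrow(row)) return(c(0, 0, 0))
    c(row$dx_px[1L], row$dz_px[1L], row$shear_v[1L])
  }
  vmax <- 2^header$bit_depth - 1
  samples <- array(0L, dim = c(n, nx, nb, nrep))
  transforms <- list()

  for (b in seq_len(nb)) {
    # reflectivity magnitude per voxel of this B-scan
    rmag <- matrix(r_z, nz, nx)
    for (nm in names(vessel_rows)) {
      vx <- which(vessel_masks[[nm]][b, ])
      if (length(vx))
        rmag[vessel_rows[[nm]], vx] <-
          pmax(rmag[vessel_rows[[nm]], vx], spec$vessel_reflectivity)
    }
    psi <- rmag * matrix(complex(real = stats::rnorm(nz * nx),
                                 imaginary = stats::rnorm(nz * nx)) /
                           sqrt(2), nz, nx)
    spect <- fringe_mat %*% psi                     # static field, repeat 1
    for (r in seq_len(nrep)) {
      if (r > 1L && length(vrows_all) && spec$flow_fraction > 0) {
        # decorrelate flowing voxels with probability flow_fraction per T_R
        sub <- psi[vrows_all, , drop = FALSE]
        flowing <- matrix(FALSE, length(vrows_all), nx)
        for (nm in names(vessel_rows)) {
          ri <- match(vessel_rows[[nm]], vrows_all)
          vx <- which(vessel_masks[[nm]][b, ])
          if (length(vx))
            flowing[ri, vx] <- TRUE
        }
        gate <- flowing &
          matrix(stats::runif(length(vrows_all) * nx) < spec$flow_fraction,
                 length(vrows_all), nx)
        if (any(gate)) {
          # fully redraw the complex reflectivity (amplitude and phase)
          nnew <- sum(gate)
          rm2 <- rmag[vrows_all, , drop = FALSE][gate]
          new_val <- rm2 * complex(real = stats::rnorm(nnew),
                                   imaginary = stats::rnorm(nnew)) / sqrt(2)
          delta <- new_val - sub[gate]
          dmat <- matrix(0i, length(vrows_all), nx)
          dmat[gate] <- delta
          spect <- spect + fringe_mat[, vrows_all, drop = FALSE] %*% dmat
          sub[gate] <- new_val
          psi[vrows_all, ] <- sub
        }
      }
      mo <- get_motion(b, r)
      sp <- spect
      if (any(mo != 0)) {
        zshift_um <- (mo[2L] + mo[3L] * (seq_len(nx) - 1)) * ax$dz_um
        sp <- sp * exp(2i * outer(k, zshift_um))
        if (mo[1L] != 0) {
          d <- mo[1L]
          d0 <- floor(d); f <- d - d0
          colix <- function(shift) {
            ix <- seq_len(nx) - shift
            pmin(pmax(ix, 1L), nx)
          }
          sp <- (1 - f) * sp[, colix(d0), drop = FALSE] +
            f * sp[, colix(d0 + 1L), drop = FALSE]
        }
      }
      fr <- env * (1 + alpha * Re(disp_phasor * sp)) +
        stats::rnorm(n * nx, 0, spec$noise_sigma)
      samples[, , b, r] <- pmin(pmax(round(fr), 0), vmax)
      transforms[[length(transforms) + 1L]] <-
        data.frame(bscan = b, repeat_idx = r, dx_px = mo[1L],
                   dz_px = mo[2L], shear_v = mo[3L])
    }
  }

  surface_depths <- list()
  if (nrow(layers)) {
    for (i in seq_len(nrow(layers)))
      surface_depths[[layers$name[i]]] <-
        matrix(layers$depth_um[i], nb, nx)
  }
  truth <- structure(
    list(surface_depths_um = surface_depths,
         vessel_masks = lapply(vessel_masks, function(m) m),
         vessel_rows = vessel_rows,
         vessel_depth_um = if (nrow(vl)) stats::setNames(vl$depth_um,
                                                         vl$name) else
           numeric(),
         z_spacing_um = ax$dz_um,
         transforms = do.call(rbind, transforms),
         flow_fraction = spec$flow_fraction,
         layers = layers),
    class = "phantom_truth")
  list(volume = raw_spectra_volume(header, samples), truth = truth)
}

#' Single-reflector phantom frame set
#'
#' A minimal raw volume with one diffuse reflecting plane at a given depth:
#' each A-scan carries a fringe `cos(2 k z + phi_x)` with an independent
#' random phase per A-scan (so mean-spectrum subtraction leaves the fringes
#' intact), optionally with injected dispersion. Used for closed-form depth
#' and dispersion-recovery checks.
#'
#' @param header a [raw_scan_header()].
#' @param z_um reflector depth (um).
#' @param modulation fringe modulation relative to the envelope.
#' @param dispersion injected `c(a2, a3)`.
#' @param noise_sigma additive noise (counts).
#' @param seed RNG seed.
#' @return a [raw_spectra_volume()].
#' @export
phantom_single_reflector <- function(header, z_um, modulation = 0.3,
                                     dispersion = c(0, 0), noise_sigma = 2,
                                     seed = 1L) {
  set.seed(seed)
  ax <- phantom_axial_grid(header)
  if (z_um >= ax$z_max_um)
    stop("phantom: reflector deeper than the depth range")
  n <- header$n_spectral_samples
  nx <- header$n_ascans_per_bscan
  lam <- header_wavelengths(header)
  env <- exp(-(lam - 850)^2 / (2 * (165 / 2.355)^2)) * 1500
  k <- ax$k
  k0 <- mean(range(k))
  phi_d <- dispersion[1L] * (k - k0)^2 + dispersion[2L] * (k - k0)^3
  vmax <- 2^header$bit_depth - 1
  samples <- array(0L, dim = c(n, nx, header$n_bscans, header$n_repeats))
  for (b in seq_len(header$n_bscans)) {
    for (r in seq_len(header$n_repeats)) {
      phi_x <- stats::runif(nx, 0, 2 * pi)
      fr <- env * (1 + modulation *
                     cos(outer(2 * k * z_um + phi_d, phi_x, `+`))) +
        stats::rnorm(n * nx, 0, noise_sigma)
      samples[, , b, r] <- pmin(pmax(round(fr), 0), vmax)
    }
  }
  raw_spectra_volume(header, samples)
}
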