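# AOSLO-style video processing (desinusoiding against a Ronchi ruling,
# full-frame NCC registration, temporal standard-deviation binning, single
# blood-cell velocimetry) and the square-wave blood-cell detectability
# model: a cell train of length L and center-to-center period Lambda moving
# at velocity v occupies a capillary cross-section with duty cycle L/Lambda;
# detecting a fully connected capillary requires dwelling for one transit
# period Lambda/v, which can be compared against the OCT-A interscan
# interval T_R.

detect_line_centers <- function(profile, min_lines = 5L) {
  n <- length(profile)
  sm <- stats::filter(profile, rep(1 / 3, 3), sides = 2L)
  sm[is.na(sm)] <- profile[is.na(sm)]
  thr <- (max(sm) + mean(sm)) / 2
  loc <- which(sm > thr &
               sm >= c(-Inf, sm[-n]) & sm > c(sm[-1L], -Inf))
  loc <- loc[loc > 1L & loc < n]
  if (length(loc) < min_lines)
    stop(sprintf("desinusoid: only %d grid lines detected (need >= %d)",
                 length(loc), min_lines))
  vapply(loc, function(i) refine_peak_parabolic(as.numeric(sm), i), 0)
}

#' Build a desinusoiding map from a Ronchi-ruling image
#'
#' Detects the vertical line centers of a grid-calibration image, fits the
#' uniform spacing they should have, and returns a monotone lookup mapping
#' each output column to the fractional input column to resample from, so
#' that after application the line spacing is uniform. Also calibrates the
#' lateral scale from the known line pitch.
#'
#' @param ronchi_image numeric matrix of a vertical-line grid (>= 5
#'   periods).
#' @param line_pitch_um physical line spacing (um).
#' @return object of class `desinusoid_map`: `lookup` (strictly increasing
#'   numeric vector over the full width), `scale_um_per_px` (um per output
#'   pixel) and `line_centers_px`.
#' @export
build_desinusoid_map <- function(ronchi_image, line_pitch_um) {
  centers <- detect_line_centers(colMeans(ronchi_image))
  nlines <- length(centers)
  width <- ncol(ronchi_image)
  spacing <- (centers[nlines] - centers[1L]) / (nlines - 1L)
  uniform <- centers[1L] + (seq_len(nlines) - 1L) * spacing
  # monotone interpolation uniform-position -> distorted position, extended
  # linearly beyond the outermost detected lines
  fit <- stats::splinefun(uniform, centers, method = "monoH.FC")
  cols <- seq_len(width)
  lookup <- numeric(width)
  inside <- cols >= uniform[1L] & cols <= uniform[nlines]
  lookup[inside] <- fit(cols[inside])
  slope_lo <- (centers[2L] - centers[1L]) / spacing
  slope_hi <- (centers[nlines] - centers[nlines - 1L]) / spacing
  lookup[cols < uniform[1L]] <-
    centers[1L] + (cols[cols < uniform[1L]] - uniform[1L]) * slope_lo
  lookup[cols > uniform[nlines]] <-
    centers[nlines] + (cols[cols > uniform[nlines]] - uniform[nlines]) *
    slope_hi
  if (any(diff(lookup) <= 0))
    stop("desinusoid: resampling map is not strictly increasing")
  structure(list(lookup = lookup,
                 scale_um_per_px = line_pitch_um / spacing,
                 line_centers_px = centers),
            class = "desinusoid_map")
}

#' Apply a desinusoiding map to an image
#'
#' Linear interpolation of each row at the fractional input columns of the
#' map; columns sampling outside the input are clamped to the edge.
#'
#' @param image numeric matrix.
#' @param map a [build_desinusoid_map()] result.
#' @export
apply_desinusoid <- function(image, map) {
  w <- ncol(image)
  xq <- pmin(pmax(map$lookup, 1), w)
  x0 <- floor(xq); x1 <- pmin(w, x0 + 1L); f <- xq - x0
  image[, x0, drop = FALSE] * rep(1 - f, each = nrow(image)) +
    image[, x1, drop = FALSE] * rep(f, each = nrow(image))
}

#' Register an AOSLO video by full-frame NCC
#'
#' Each frame is translated by the integer shift maximizing its normalized
#' cross-correlation with the reference frame (brute force over
#' `+/- max_shift` px on the overlap region), with optional parabolic
#' subpixel refinement of the reported shifts.
#'
#' @param video an [aoslo_video()].
#' @param reference_index reference frame; `NULL` selects the frame with the
#'   highest NCC against the temporal mean image.
#' @param max_shift search half-range (px).
#' @param subpixel also report parabolic subpixel shift estimates.
#' @return list with `video` (registered, zero-filled borders) and `shifts`
#'   (data.frame `frame`, `dr_px`, `dc_px`, `ncc`, and `dr_sub`/`dc_sub`
#'   when `subpixel`).
#' @export
register_video <- function(video, reference_index = 1L, max_shift = 10L,
                           subpixel = FALSE) {
  fr <- video$frames
  nf <- dim(fr)[3L]
  if (is.null(reference_index)) {
    mu <- apply(fr, c(1L, 2L), mean)
    sims <- vapply(seq_len(nf), function(i) ncc_images(mu, fr[, , i]), 0)
    reference_index <- which.max(sims)
  }
  if (reference_index < 1L || reference_index > nf)
    stop("register_video: reference index out of range")
  ref <- fr[, , reference_index]
  out <- fr
  shifts <- data.frame(frame = seq_len(nf), dr_px = 0L, dc_px = 0L, ncc = 1)
  if (subpixel) { shifts$dr_sub <- 0; shifts$dc_sub <- 0 }
  rng <- (-max_shift):max_shift
  for (f in seq_len(nf)) {
    if (f == reference_index) next
    mov <- fr[, , f]
    cc <- matrix(-1, length(rng), length(rng))
    for (i in seq_along(rng)) {
      for (j in seq_along(rng)) {
        cc[i, j] <- ncc_int_shift(ref, mov, rng[i], rng[j])
      }
    }
    best <- which(cc == max(cc), arr.ind = TRUE)[1L, ]
    dr <- rng[best[1L]]; dc <- rng[best[2L]]
    out[, , f] <- shift_int(mov, dr, dc)
    shifts$dr_px[f] <- dr; shifts$dc_px[f] <- dc
    shifts$ncc[f] <- cc[best[1L], best[2L]]
    if (subpixel) {
      shifts$dr_sub[f] <- rng[1L] - 1 +
        refine_peak_parabolic(cc[, best[2L]], best[1L])
      shifts$dc_sub[f] <- rng[1L] - 1 +
        refine_peak_parabolic(cc[best[1L], ], best[2L])
    }
  }
  list(video = aoslo_video(out, video$timestamps_s, video$scale_um_per_px),
       shifts = shifts, reference_index = reference_index)
}

#' Temporal standard-deviation images over consecutive frame bins
#'
#' Splits the video into non-overlapping consecutive bins of `bin_size`
#' frames and computes the per-pixel temporal standard deviation within each
#' bin; moving blood cells light up along their path.
#'
#' @param video a registered [aoslo_video()].
#' @param bin_size frames per bin (>= 2).
#' @return 3-D array `[row, column, bin]` with `floor(n_frames/bin_size)`
#'   bins.
#' @export
temporal_std_bins <- function(video, bin_size = 10L) {
  bin_size <- as.integer(bin_size)
  if (bin_size < 2L) stop("temporal_std_bins: bin_size must be >= 2")
  nf <- dim(video$frames)[3L]
  nbin <- nf %/% bin_size
  if (nbin < 1L) stop("temporal_std_bins: video shorter than one bin")
  out <- array(0, dim = c(dim(video$frames)[1:2], nbin))
  for (b in seq_len(nbin)) {
    idx <- ((b - 1L) * bin_size + 1L):(b * bin_size)
    out[, , b] <- apply(video$frames[, , idx, drop = FALSE], c(1L, 2L),
                        stats::sd)
  }
  out
}

#' Track a bright cell through a registered video
#'
#' Threshold-plus-centroid tracking inside a window that follows the cell
#' from a user-marked starting position (the intended use is manual seeding
#' on the temporal-SD image).
#'
#' @param video a registered [aoslo_video()].
#' @param start_xy starting `c(x, y)` (column, row) of the cell.
#' @param window_px square search window side.
#' @param quantile_thr intensity quantile defining the cell pixels within
#'   the window.
#' @return data.frame `time_s`, `x_px`, `y_px` with attribute
#'   `scale_um_per_px` (a cell track usable by [estimate_velocity()]).
#' @export
track_bright_cell <- function(video, start_xy, window_px = 21L,
                              quantile_thr = 0.9) {
  fr <- video$frames
  nf <- dim(fr)[3L]
  h <- dim(fr)[1L]; w <- dim(fr)[2L]
  r <- (window_px - 1L) %/% 2L
  cx <- start_xy[1L]; cy <- start_xy[2L]
  track <- data.frame(time_s = video$timestamps_s, x_px = NA_real_,
                      y_px = NA_real_)
  for (f in seq_len(nf)) {
    x1 <- max(1L, round(cx) - r); x2 <- min(w, round(cx) + r)
    y1 <- max(1L, round(cy) - r); y2 <- min(h, round(cy) + r)
    win <- fr[y1:y2, x1:x2, f]
    thr <- stats::quantile(win, quantile_thr, names = FALSE)
    sel <- which(win >= thr, arr.ind = TRUE)
    wts <- win[sel] - min(win)
    cy <- y1 - 1L + sum(sel[, 1L] * wts) / sum(wts)
    cx <- x1 - 1L + sum(sel[, 2L] * wts) / sum(wts)
    track$x_px[f] <- cx; track$y_px[f] <- cy
  }
  attr(track, "scale_um_per_px") <- video$scale_um_per_px
  track
}

#' Estimate cell velocity from a track
#'
#' Total path length (um) divided by elapsed time; also reports the
#' least-squares slope of cumulative distance against time.
#'
#' @param track data.frame with `time_s`, `x_px`, `y_px` (e.g. from
#'   [track_bright_cell()] or the phantom's true track with columns renamed
#'   accordingly) and attribute or argument `scale_um_per_px`.
#' @param scale_um_per_px lateral scale; default: the track attribute.
#' @return list with `velocity_um_s` (path length / elapsed time) and
#'   `fit_slope_um_s`.
#' @export
estimate_velocity <- function(track, scale_um_per_px = NULL) {
  scale <- scale_um_per_px %||% attr(track, "scale_um_per_px")
  if (is.null(scale)) stop("estimate_velocity: no lateral scale available")
  if (nrow(track) < 2L) stop("estimate_velocity: need >= 2 observations")
  dt <- track$time_s[nrow(track)] - track$time_s[1L]
  if (dt <= 0) stop("estimate_velocity: zero elapsed time")
  seg <- sqrt(diff(track$x_px)^2 + diff(track$y_px)^2) * scale
  cum <- c(0, cumsum(seg))
  list(velocity_um_s = sum(seg) / dt,
       fit_slope_um_s = unname(stats::coef(
         stats::lm(cum ~ track$time_s))[2L]))
}

#' Square-wave blood-cell detectability model
#'
#' For a cell train of length `L`, center-to-center period `Lambda` and
#' velocity `v`: duty cycle `L/Lambda` (fraction of time a cell occupies a
#' capillary cross-section), transit period `Lambda/v`, and required dwell
#' time equal to one transit period — the scan duration needed before every
#' cross-section of the capillary has been occupied at least once.
#'
#' @param cell_length_um cell length L (um), `0 < L <= Lambda`.
#' @param cell_spacing_um center-to-center period Lambda (um).
#' @param velocity_um_s cell velocity v (um/s), > 0.
#' @return object of class `cell_train_model` with fields `cell_length_um`,
#'   `cell_spacing_um`, `velocity_um_s`, `duty_cycle`, `transit_period_s`,
#'   `required_dwell_s`.
#' @export
square_wave_model <- function(cell_length_um, cell_spacing_um,
                              velocity_um_s) {
  if (cell_length_um <= 0) stop("square_wave_model: cell length must be > 0")
  if (cell_length_um > cell_spacing_um)
    stop("square_wave_model: cell length exceeds spacing")
  if (velocity_um_s <= 0) stop("square_wave_model: velocity must be > 0")
  period <- cell_spacing_um / velocity_um_s
  structure(list(cell_length_um = cell_length_um,
                 cell_spacing_um = cell_spacing_um,
                 velocity_um_s = velocity_um_s,
                 duty_cycle = cell_length_um / cell_spacing_um,
                 transit_period_s = period,
                 required_dwell_s = period),
            class = "cell_train_model")
}

#' @export
print.cell_train_model <- function(x, ...) {
  cat(sprintf(paste0("cell_train_model: L = %.3g um, Lambda = %.3g um, ",
                     "v = %.3g um/s\n  duty cycle %.1f%%, required dwell ",
                     "%.2f s\n"),
              x$cell_length_um, x$cell_spacing_um, x$velocity_um_s,
              100 * x$duty_cycle, x$required_dwell_s))
  invisible(x)
}

#' Ratio of required dwell time to an interscan interval
#'
#' @param model a [square_wave_model()].
#' @param t_r_ms interscan interval(s) T_R in milliseconds.
#' @return `required_dwell_s / (t_r_ms / 1000)`, vectorized over `t_r_ms`.
#' @export
interval_ratio <- function(model, t_r_ms) {
  model$required_dwell_s / (t_r_ms / 1e3)
}

#' Monte-Carlo occupancy probability of the square-wave model
#'
#' Probability that a cell occupies a fixed capillary cross-section in at
#' least one of two frames separated by `t_r_ms`, over random train phases.
#' For `T_R` much shorter than the transit period this approaches the duty
#' cycle — the mechanism behind apparent capillary dropout at short
#' interscan intervals.
#'
#' @param model a [square_wave_model()].
#' @param t_r_ms interscan interval (ms).
#' @param n_trials Monte-Carlo trials.
#' @param seed RNG seed.
#' @return detection probability estimate.
#' @export
occupancy_probability <- function(model, t_r_ms, n_trials = 1e5,
                                  seed = 1L) {
  set.seed(seed)
  lam <- model$cell_spacing_um
  phase <- stats::runif(n_trials, 0, lam)
  shift <- model$velocity_um_s * t_r_ms / 1e3
  occ1 <- phase %% lam < model$cell_length_um
  occ2 <- (phase + shift) %% lam < model$cell_length_um
  mean(occ1 | occ2)
}
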