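# AOSLO-style confocal reflectance video phantom: a train of bright blood
# cells translating along a horizontal capillary at constant velocity, with
# whole-frame translation jitter emulating residual eye motion. Returns the
# true cell track for velocimetry recovery tests.

#' AOSLO video container
#'
#' @param frames 3-D array `[row, column, frame]`.
#' @param timestamps_s strictly increasing per-frame acquisition times (s).
#' @param scale_um_per_px lateral scale.
#' @return object of class `aoslo_video`.
#' @export
aoslo_video <- function(frames, timestamps_s, scale_um_per_px) {
  stopifnot(length(dim(frames)) == 3L,
            dim(frames)[3L] == length(timestamps_s))
  if (any(diff(timestamps_s) <= 0))
    stop("aoslo_video: timestamps must be strictly increasing")
  structure(list(frames = frames, timestamps_s = timestamps_s,
                 scale_um_per_px = scale_um_per_px),
            class = "aoslo_video")
}

#' @export
print.aoslo_video <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("aoslo_video: %d x %d px, %d frames, %.3g um/px\n",
              d[1L], d[2L], d[3L], x$scale_um_per_px))
  invisible(x)
}

#' Generate an AOSLO-style capillary video with ground truth
#'
#' Cells of length `cell_length_um` spaced `cell_spacing_um` apart
#' (center-to-center) translate along a horizontal capillary at
#' `cell_velocity_um_s`; every frame is perturbed by an integer translation
#' jitter drawn from a rounded normal of SD `jitter_px`.
#'
#' @param cell_velocity_um_s cell velocity (um/s), >= 0.
#' @param cell_length_um cell length (um); must not exceed the spacing.
#' @param cell_spacing_um center-to-center cell period (um).
#' @param frame_rate_hz frame rate (Hz), > 0.
#' @param n_frames number of frames.
#' @param scale_um_per_px lateral scale (um/px).
#' @param jitter_px SD of the per-frame translation jitter (0 for none).
#' @param width_px,height_px frame size.
#' @param seed RNG seed.
#' @return list with `video` (an [aoslo_video()]), `track` (data.frame
#'   `time_s`, `x_px`, `y_px`, `length_um`: true pre-jitter centroid of one
#'   tracked cell) and `jitter` (the injected per-frame `c(dr, dc)` shifts).
#' @export
generate_aoslo_video <- function(cell_velocity_um_s,
                                 cell_length_um = 8.4,
                                 cell_spacing_um = 122,
                                 frame_rate_hz = 16.6,
                                 n_frames = 40L,
                                 scale_um_per_px = 1.0,
                                 jitter_px = 0.5,
                                 width_px = 128L, height_px = 64L,
                                 seed = 1L) {
  if (cell_velocity_um_s < 0) stop("aoslo phantom: velocity must be >= 0")
  if (frame_rate_hz <= 0) stop("aoslo phantom: frame rate must be > 0")
  if (cell_length_um > cell_spacing_um)
    stop("aoslo phantom: cell length exceeds cell spacing")
  set.seed(seed)
  ts <- (seq_len(n_frames) - 1) / frame_rate_hz
  y0 <- height_px / 2
  x_start <- width_px / 5
  sigma_x <- cell_length_um / 2.355 / scale_um_per_px
  sigma_y <- max(1.2, 0.4 * sigma_x)
  tex <- gaussian_blur(matrix(stats::rnorm(height_px * width_px),
                              height_px, width_px), 2)
  tex <- 0.04 * tex / max(stats::sd(tex), 1e-12)
  yy <- matrix(seq_len(height_px), height_px, width_px)
  xx <- matrix(seq_len(width_px), height_px, width_px, byrow = TRUE)
  capillary <- 0.05 * exp(-(yy - y0)^2 / (2 * (2 * sigma_y)^2))
  frames <- array(0, dim = c(height_px, width_px, n_frames))
  track <- data.frame(time_s = ts, x_px = NA_real_, y_px = y0,
                      length_um = cell_length_um)
  jit <- matrix(0L, n_frames, 2L)
  n_cells_back <- ceiling(width_px * scale_um_per_px / cell_spacing_um) + 2L
  for (f in seq_len(n_frames)) {
    shift_um <- cell_velocity_um_s * ts[f]
    img <- 0.15 + tex + capillary
    for (m in (-n_cells_back):1L) {
      xc <- x_start + (shift_um + m * cell_spacing_um) / scale_um_per_px
      if (xc < -4 * sigma_x || xc > width_px + 4 * sigma_x) next
      img <- img + 0.8 * exp(-((xx - xc)^2 / (2 * sigma_x^2) +
                               (yy - y0)^2 / (2 * sigma_y^2)))
    }
    track$x_px[f] <- x_start + shift_um / scale_um_per_px
    img <- img + matrix(stats::rnorm(height_px * width_px, 0, 0.02),
                        height_px, width_px)
    if (jitter_px > 0) {
      jit[f, ] <- as.integer(round(stats::rnorm(2L, 0, jitter_px)))
      img <- shift_int(img, jit[f, 1L], jit[f, 2L], fill = 0.15)
    }
    frames[, , f] <- pmax(img, 0)
  }
  list(video = aoslo_video(frames, ts, scale_um_per_px),
       track = track, jitter = jit)
}
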