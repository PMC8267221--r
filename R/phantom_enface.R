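# Synthetic en-face vasculature: branching tubes rasterized onto a pixel
# grid, used both as a standalone segmentation fixture (bright tubes on a
# textured background) and as the per-plexus vessel geometry of the raw
# spectral phantom. Branch calibers decay multiplicatively (Murray-law-like);
# only density and caliber statistics are contractual, the morphology is a
# fixture choice.

disc_offsets <- function(radius_px) {
  r <- max(1, radius_px)
  ri <- ceiling(r)
  g <- expand.grid(dy = -ri:ri, dx = -ri:ri)
  g <- g[g$dy^2 + g$dx^2 <= r^2, , drop = FALSE]
  as.matrix(g)
}

#' Generate a branching vessel-tree mask
#'
#' Grows random-walk tubes from the image borders, branching with decaying
#' caliber, and stamps discs along each path until the requested foreground
#' density is reached (stamping stops mid-tube at the target, so the achieved
#' density overshoots by at most one disc).
#'
#' @param height_px,width_px mask size (rows x columns).
#' @param scale_um_per_px lateral scale.
#' @param target_density_pct requested vessel density in percent, in (0, 60).
#' @param caliber_range_um vessel diameter range (um); must be >= 2 px at the
#'   given scale.
#' @param max_attempts tube attempts before giving up.
#' @return logical matrix.
#' @keywords internal
generate_vessel_tree_mask <- function(height_px, width_px,
                                      scale_um_per_px = 1.5,
                                      target_density_pct = 25,
                                      caliber_range_um = c(4, 12),
                                      max_attempts = 500L) {
  mask <- matrix(FALSE, height_px, width_px)
  if (target_density_pct <= 0) return(mask)
  if (target_density_pct >= 60)
    stop("vessel tree: target density must be in (0, 60) percent")
  cal_px <- sort(caliber_range_um) / scale_um_per_px
  if (cal_px[1L] < 2)
    stop("vessel tree: minimum caliber below 2 px at this scale")
  target_n <- target_density_pct / 100 * height_px * width_px
  n_on <- 0L
  attempts <- 0L
  max_steps <- 4L * (height_px + width_px)
  while (n_on < target_n) {
    attempts <- attempts + 1L
    if (attempts > max_attempts)
      stop(sprintf(paste0("vessel tree: target density %g%% unreachable ",
                          "after %d attempts"),
                   target_density_pct, max_attempts))
    # root on a random border, heading inward
    side <- sample.int(4L, 1L)
    pos <- switch(side,
                  c(stats::runif(1, 1, height_px), 1),
                  c(stats::runif(1, 1, height_px), width_px),
                  c(1, stats::runif(1, 1, width_px)),
                  c(height_px, stats::runif(1, 1, width_px)))
    ang <- switch(side, 0, pi, pi / 2, -pi / 2) + stats::rnorm(1, 0, 0.3)
    queue <- list(list(pos = pos, ang = ang,
                       cal = stats::runif(1, 0.7, 1) * cal_px[2L]))
    while (length(queue) && n_on < target_n) {
      tube <- queue[[1L]]; queue <- queue[-1L]
      pos <- tube$pos; ang <- tube$ang; cal <- tube$cal
      for (step in seq_len(max_steps)) {
        pos <- pos + c(sin(ang), cos(ang))
        if (pos[1L] < 1 || pos[1L] > height_px ||
            pos[2L] < 1 || pos[2L] > width_px) break
        ang <- ang + stats::rnorm(1, 0, 0.12)
        cal <- max(cal * 0.999, cal_px[1L])
        off <- disc_offsets(cal / 2)
        yy <- round(pos[1L]) + off[, "dy"]
        xx <- round(pos[2L]) + off[, "dx"]
        ok <- yy >= 1L & yy <= height_px & xx >= 1L & xx <= width_px
        idx <- cbind(yy[ok], xx[ok])
        new <- !mask[idx]
        if (any(new)) {
          mask[idx[new, , drop = FALSE]] <- TRUE
          n_on <- n_on + sum(new)
          if (n_on >= target_n) break
        }
        if (stats::runif(1) < 0.008 && cal > 1.4 * cal_px[1L]) {
          queue[[length(queue) + 1L]] <-
            list(pos = pos,
                 ang = ang + sample(c(-1, 1), 1L) * stats::runif(1, 0.4, 1.0),
                 cal = max(cal * 0.75, cal_px[1L]))
        }
      }
    }
  }
  mask
}

#' Generate a synthetic en-face vasculature image with ground truth
#'
#' Produces a noisy grayscale image of bright vessel tubes over a smoothly
#' textured background together with the exact binary ground-truth mask. The
#' achieved mask density is within +/- 2 percentage points of the target (by
#' construction it lands just above the target). Deterministic for a fixed
#' seed.
#'
#' @param width_px,height_px image size.
#' @param scale_um_per_px lateral scale (um/px).
#' @param target_density_pct vessel density target in percent, in (0, 60);
#'   0 yields a blank mask.
#' @param caliber_range_um vessel diameter range in um.
#' @param seed RNG seed.
#' @param vessel_intensity,background,texture_sd,noise_sd image model
#'   parameters: vessel brightness over the background level, the SD of the
#'   slow (illumination-scale) background texture, and the SD of the
#'   uncorrelated pixel noise. The texture is smooth at a scale well above
#'   the vessel calibers so that nothing tube-like exists in the image that
#'   the ground-truth mask does not label.
#' @return list with `image` (an [enface_image()]) and `mask` (a
#'   [vessel_mask()]).
#' @export
generate_enface_vasculature <- function(width_px, height_px,
                                        scale_um_per_px = 1.5,
                                        target_density_pct = 25,
                                        caliber_range_um = c(4, 12),
                                        seed = 1L,
                                        vessel_intensity = 0.55,
                                        background = 0.25,
                                        texture_sd = 0.05,
                                        noise_sd = 0.05) {
  set.seed(seed)
  mask <- generate_vessel_tree_mask(height_px, width_px, scale_um_per_px,
                                    target_density_pct, caliber_range_um)
  tex <- gaussian_blur(matrix(stats::rnorm(height_px * width_px),
                              height_px, width_px), 6)
  tex <- tex / max(stats::sd(tex), 1e-12)
  img <- background + texture_sd * tex +
    vessel_intensity * gaussian_blur(matrix(as.numeric(mask),
                                            height_px, width_px), 1) +
    stats::rnorm(height_px * width_px, 0, noise_sd)
  img <- pmax(img, 0)
  list(image = enface_image(img, scale_um_per_px, slab = "SYNTHETIC",
                            projection = "mean"),
       mask = vessel_mask(mask, scale_um_per_px))
}
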