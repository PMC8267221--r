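# Lateral image-scale calibration: the nominal pixel size predicted from
# scan geometry and the retinal magnification factor (RMF), and the
# empirical scale recovered by a closed-form least-squares similarity fit
# (scale, rotation, translation) of image landmarks onto a calibrated
# micrograph. Axial-length adjustment of the RMF is deliberately not
# modeled; the RMF is a direct input.

#' Optical scale model
#'
#' @param scan_angle_deg optical scan angle (degrees).
#' @param n_ascans A-scans across the scan angle.
#' @param rmf_um_per_deg retinal magnification factor (um of retina per
#'   degree of scan angle); 100 um/degree is a typical rodent-scale value.
#' @export
optical_scale_model <- function(scan_angle_deg, n_ascans,
                                rmf_um_per_deg = 100) {
  if (any(c(scan_angle_deg, n_ascans, rmf_um_per_deg) <= 0))
    stop("optical_scale_model: all parameters must be positive")
  structure(list(scan_angle_deg = scan_angle_deg,
                 n_ascans = as.integer(n_ascans),
                 rmf_um_per_deg = rmf_um_per_deg),
            class = "optical_scale_model")
}

#' Nominal lateral pixel size from scan geometry
#'
#' `scan_angle_deg * rmf_um_per_deg / n_ascans` micrometres per pixel.
#'
#' @param model an [optical_scale_model()].
#' @return nominal scale in um/px.
#' @export
nominal_pixel_size <- function(model) {
  model$scan_angle_deg * model$rmf_um_per_deg / model$n_ascans
}

#' Point correspondences between an image and a calibrated micrograph
#'
#' @param xa_px,ya_px landmark coordinates in image A (pixels).
#' @param xb_um,yb_um matching coordinates in image B (micrometres).
#' @return object of class `point_correspondences`.
#' @export
point_correspondences <- function(xa_px, ya_px, xb_um, yb_um) {
  n <- length(xa_px)
  stopifnot(length(ya_px) == n, length(xb_um) == n, length(yb_um) == n)
  if (n < 2L) stop("point_correspondences: need at least 2 pairs")
  if (anyDuplicated(cbind(xa_px, ya_px)))
    stop("point_correspondences: duplicate source points")
  structure(list(a = cbind(x = xa_px, y = ya_px),
                 b = cbind(x = xb_um, y = yb_um)),
            class = "point_correspondences")
}

#' Read point correspondences from CSV
#'
#' Expects columns `xA_px`, `yA_px`, `xB_um`, `yB_um`.
#' @param path `.csv` path.
#' @export
read_correspondences_csv <- function(path) {
  d <- utils::read.csv(path)
  need <- c("xA_px", "yA_px", "xB_um", "yB_um")
  if (!all(need %in% names(d)))
    stop(sprintf("correspondences CSV must have columns: %s",
                 paste(need, collapse = ", ")))
  point_correspondences(d$xA_px, d$yA_px, d$xB_um, d$yB_um)
}

#' Least-squares similarity fit of point correspondences
#'
#' Closed-form orthogonal-Procrustes-with-scale solution for the similarity
#' transform (scale, rotation, translation) minimizing the summed squared
#' residuals of `B - (s R A + t)`; exact (zero residual) on noiseless
#' transformed point sets.
#'
#' @param points a [point_correspondences()] (A in px, B in um).
#' @return object of class `similarity_fit`: `scale_um_per_px`,
#'   `rotation_deg`, `translation_um` (length 2), `rms_residual_um`.
#' @export
fit_similarity <- function(points) {
  a <- points$a; b <- points$b
  n <- nrow(a)
  mu_a <- colMeans(a); mu_b <- colMeans(b)
  ac <- sweep(a, 2L, mu_a); bc <- sweep(b, 2L, mu_b)
  var_a <- sum(ac^2) / n
  if (var_a <= 0)
    stop("fit_similarity: source points are coincident (degenerate)")
  cov <- crossprod(bc, ac) / n           # 2x2, maps A-space to B-space
  sv <- svd(cov)
  s_mat <- diag(c(1, sign(det(sv$u %*% t(sv$v)))))
  r_mat <- sv$u %*% s_mat %*% t(sv$v)
  scale <- sum(diag(diag(sv$d) %*% s_mat)) / var_a
  if (scale <= 0) stop("fit_similarity: non-positive scale (degenerate)")
  trans <- mu_b - scale * as.vector(r_mat %*% mu_a)
  pred <- sweep(scale * t(r_mat %*% t(a)), 2L, -trans)
  rms <- sqrt(mean(rowSums((b - pred)^2)))
  structure(list(scale_um_per_px = scale,
                 rotation_deg = atan2(r_mat[2L, 1L], r_mat[1L, 1L]) *
                   180 / pi,
                 translation_um = unname(trans),
                 rms_residual_um = rms,
                 n = n),
            class = "similarity_fit")
}

#' @export
print.similarity_fit <- function(x, ...) {
  cat(sprintf(paste0("similarity_fit: scale %.4g um/px, rotation %.3g deg, ",
                     "RMS residual %.3g um (n = %d)\n"),
              x$scale_um_per_px, x$rotation_deg, x$rms_residual_um, x$n))
  invisible(x)
}

#' Discrepancy between nominal and fitted lateral scales
#'
#' @param nominal_um_per_px nominal scale (e.g. from
#'   [nominal_pixel_size()]).
#' @param fitted_um_per_px empirically fitted scale (e.g. from
#'   [fit_similarity()]).
#' @return list with `difference_um_per_px` (`fitted - nominal`) and
#'   `ratio` (`fitted / nominal`).
#' @export
scale_discrepancy <- function(nominal_um_per_px, fitted_um_per_px) {
  if (nominal_um_per_px <= 0 || fitted_um_per_px <= 0)
    stop("scale_discrepancy: scales must be positive")
  list(difference_um_per_px = fitted_um_per_px - nominal_um_per_px,
       ratio = fitted_um_per_px / nominal_um_per_px)
}
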