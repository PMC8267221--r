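# BM-scan registration and full-spectrum amplitude decorrelation angiography
# (FSADA). Frames within a BM-scan are registered to the first frame by
# translation plus vertical shear (coarse integer NCC grid followed by
# Nelder-Mead refinement); the decorrelation of linear amplitudes between
# lag-p frame pairs provides the flow contrast, optionally with VISTA-style
# pair skipping (pair_step > 1 lengthens the effective interscan interval).

#' BM-scan container
#'
#' A stack of `N >= 2` reconstructed linear-amplitude B-scans acquired at one
#' slow-axis location, `repetition_time_ms` apart.
#'
#' @param frames 3-D array `[depth, A-scan, frame]` or list of equally
#'   shaped matrices.
#' @param repetition_time_ms interscan interval T_R (ms).
#' @return object of class `bm_scan`.
#' @export
bm_scan <- function(frames, repetition_time_ms) {
  if (is.list(frames)) {
    stopifnot(length(unique(lapply(frames, dim))) == 1L)
    frames <- array(unlist(frames),
                    dim = c(dim(frames[[1L]]), length(frames)))
  }
  stopifnot(length(dim(frames)) == 3L)
  if (dim(frames)[3L] < 2L) stop("bm_scan: need at least 2 frames")
  structure(list(frames = frames, repetition_time_ms = repetition_time_ms),
            class = "bm_scan")
}

#' Register the frames of a BM-scan
#'
#' Frame 1 is the reference (identity transform). Every other frame is
#' warped (bilinear) under the translation-plus-vertical-shear transform
#' maximizing its normalized cross-correlation (NCC) with the reference: a
#' coarse integer grid over `(dx, dz)` within `+/- max_shift` px is followed
#' by Nelder-Mead refinement of `(dx, dz, shear)`. The identity transform is
#' the fallback, so the reported NCC never decreases. Warped samples leaving
#' the grid are filled with the reference so they contribute no spurious
#' decorrelation.
#'
#' @param scan a [bm_scan()].
#' @param max_shift coarse search half-range (px).
#' @param shear_bound shear magnitude bound (axial px per lateral px).
#' @return list with `scan` (registered [bm_scan()]) and `transforms`
#'   (data.frame `frame`, `dx_px`, `dz_px`, `shear_v`, `ncc_before`,
#'   `ncc_after`).
#' @export
register_bm_scan <- function(scan, max_shift = 8L, shear_bound = 0.05) {
  fr <- scan$frames
  nfr <- dim(fr)[3L]
  ref <- fr[, , 1L]
  out <- fr
  rows <- list(data.frame(frame = 1L, dx_px = 0, dz_px = 0, shear_v = 0,
                          ncc_before = 1, ncc_after = 1))
  for (f in 2L:nfr) {
    mov <- fr[, , f]
    ncc0 <- ncc_images(ref, mov)
    # coarse integer translation: FFT cross-correlation peak, checked
    # against the identity by actual NCC
    pk <- xcorr_peak_shift(ref, mov, max_shift)
    best <- c(0L, 0L); best_ncc <- ncc0
    v <- ncc_int_shift(ref, mov, pk[["dr"]], pk[["dc"]])
    if (v > best_ncc) { best_ncc <- v; best <- c(pk[["dc"]], pk[["dr"]]) }
    # simplex refinement of (dx, dz, shear)
    cost <- function(par) {
      if (abs(par[1L]) > max_shift + 2 || abs(par[2L]) > max_shift + 2 ||
          abs(par[3L]) > shear_bound)
        return(2)
      -ncc_images(ref, warp_bscan(mov, par[1L], par[2L], par[3L]))
    }
    o <- stats::optim(c(best[1L], best[2L], 0), cost,
                      method = "Nelder-Mead",
                      control = list(maxit = 200L, reltol = 1e-8))
    par <- o$par
    par[1L] <- min(max(par[1L], -(max_shift + 2)), max_shift + 2)
    par[2L] <- min(max(par[2L], -(max_shift + 2)), max_shift + 2)
    par[3L] <- min(max(par[3L], -shear_bound), shear_bound)
    ncc1 <- -cost(par)
    if (ncc1 < ncc0) {           # fall back to identity
      par <- c(0, 0, 0); ncc1 <- ncc0
      w <- mov
    } else {
      w <- warp_bscan(mov, par[1L], par[2L], par[3L])
      w[!is.finite(w)] <- ref[!is.finite(w)]
    }
    out[, , f] <- w
    rows[[f]] <- data.frame(frame = f, dx_px = par[1L], dz_px = par[2L],
                            shear_v = par[3L], ncc_before = ncc0,
                            ncc_after = ncc1)
  }
  list(scan = bm_scan(out, scan$repetition_time_ms),
       transforms = do.call(rbind, rows))
}

#' Full-spectrum amplitude decorrelation angiography of a BM-scan
#'
#' Per pixel, over all `P` frame pairs at lag `pair_step`,
#' `D = 1 - (1/P) * sum_p A_n A_(n+p) / (0.5 * (A_n^2 + A_(n+p)^2))`,
#' clipped to `[0, 1]`. Pixels where both amplitudes vanish contribute no
#' decorrelation (`D = 0` there). `pair_step > 1` skips frames (variable
#' interscan time analysis), giving an effective interscan interval of
#' `pair_step * T_R`. Amplitudes must be linear; log-scaled input (detected
#' by negative values) is rejected.
#'
#' @param scan a registered [bm_scan()].
#' @param pair_step lag between paired frames (default 1 = adjacent).
#' @return an `angio_bscan`: list with `decorrelation` matrix in `[0, 1]`,
#'   `mask` (structural mask once applied, else NULL), `pair_step` and
#'   `effective_interval_ms`.
#' @export
fsada <- function(scan, pair_step = 1L) {
  fr <- scan$frames
  nfr <- dim(fr)[3L]
  pair_step <- as.integer(pair_step)
  if (nfr < pair_step + 1L)
    stop(sprintf("fsada: need at least pair_step + 1 = %d frames, have %d",
                 pair_step + 1L, nfr))
  if (min(fr) < 0)
    stop("fsada: negative amplitudes; input looks log-scaled, use linear")
  acc <- matrix(0, dim(fr)[1L], dim(fr)[2L])
  np <- nfr - pair_step
  for (i in seq_len(np)) {
    a <- fr[, , i]
    b <- fr[, , i + pair_step]
    den <- 0.5 * (a^2 + b^2)
    ratio <- ifelse(den == 0, 1, a * b / pmax(den, .Machine$double.xmin))
    acc <- acc + ratio
  }
  d <- pmin(pmax(1 - acc / np, 0), 1)
  structure(list(decorrelation = d, mask = NULL, pair_step = pair_step,
                 effective_interval_ms =
                   pair_step * scan$repetition_time_ms),
            class = "angio_bscan")
}

#' Structural-amplitude masking of an angiogram
#'
#' Sets the decorrelation to zero wherever the structural amplitude falls
#' below the given quantile of the frame's amplitude distribution, removing
#' noise-floor false-positive flow. With `threshold_quantile = 0` the
#' angiogram is unchanged; as the quantile approaches 1 everything below the
#' maximum is zeroed (pixels tied with the maximum survive the strict `<`).
#'
#' @param angio an `angio_bscan` from [fsada()].
#' @param structure structural amplitude B-scan of matching shape (e.g. the
#'   mean registered frame).
#' @param threshold_quantile amplitude quantile in `[0, 1]`.
#' @return the angiogram with masked `decorrelation` and a recorded `mask`
#'   (TRUE = kept).
#' @export
mask_structural <- function(angio, structure, threshold_quantile = 0.5) {
  stopifnot(identical(dim(angio$decorrelation), dim(structure)))
  if (threshold_quantile < 0 || threshold_quantile > 1)
    stop("mask_structural: quantile must be in [0, 1]")
  thr <- stats::quantile(structure, threshold_quantile, names = FALSE)
  keep <- structure >= thr
  if (threshold_quantile == 0) keep[] <- TRUE
  d <- angio$decorrelation
  d[!keep] <- 0
  angio$decorrelation <- d
  angio$mask <- keep
  angio
}

#' Angiographic volume from a reconstructed structural volume
#'
#' Registers each BM-scan, averages the registered frames into a structural
#' volume, computes FSADA per B-scan location and applies structural
#' masking.
#'
#' @param volume a [structural_volume()] with `n_repeats >= 2` (linear
#'   amplitudes).
#' @param pair_step FSADA pair lag (VISTA when > 1).
#' @param register run BM-scan registration (default TRUE; phantoms without
#'   injected motion may skip it for speed).
#' @param mask_quantile structural masking quantile (NULL for none).
#' @return list with `angio` (3-D decorrelation array
#'   `[depth, A-scan, B-scan]`), `structure` (mean registered amplitude,
#'   same shape), `transforms` (per-frame registration table) and
#'   `pair_step`.
#' @export
fsada_volume <- function(volume, pair_step = 1L, register = TRUE,
                         mask_quantile = 0.5) {
  stopifnot(inherits(volume, "structural_volume"))
  if (volume$log_display)
    stop("fsada_volume: amplitudes are log-scaled; angiography needs linear")
  d <- dim(volume$amplitude)
  if (d[4L] < 2L) stop("fsada_volume: need >= 2 repeats")
  angio <- array(0, dim = d[1:3])
  struct <- array(0, dim = d[1:3])
  tr <- list()
  for (b in seq_len(d[3L])) {
    scan <- bm_scan(volume$amplitude[, , b, ], volume$repetition_time_ms)
    if (register) {
      reg <- register_bm_scan(scan)
      scan <- reg$scan
      t_b <- reg$transforms
      t_b$bscan <- b
      tr[[b]] <- t_b
    }
    ab <- fsada(scan, pair_step)
    sb <- apply(scan$frames, c(1L, 2L), mean)
    if (!is.null(mask_quantile)) ab <- mask_structural(ab, sb, mask_quantile)
    angio[, , b] <- ab$decorrelation
    struct[, , b] <- sb
  }
  list(angio = angio, structure = struct,
       transforms = if (length(tr)) do.call(rbind, tr) else NULL,
       pair_step = pair_step,
       z_spacing_um = volume$z_spacing_um,
       effective_interval_ms = pair_step * volume$repetition_time_ms)
}
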