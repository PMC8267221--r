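# Low-level image helpers shared by the reconstruction, angiography and
# segmentation modules. All windowed filters use symmetric (reflective)
# border padding; connected components use 8-connectivity.

#' Round half away from zero
#'
#' Used wherever micrometre offsets are converted to pixel indices, so that
#' +0.5 px rounds up and -0.5 px rounds down regardless of the banker's
#' rounding of [round()].
#'
#' @param x numeric vector.
#' @return integer vector.
#' @keywords internal
round_half_away <- function(x) {
  as.integer(sign(x) * floor(abs(x) + 0.5))
}

# symmetric (mirror-with-edge) padding of a matrix by r rows/cols
pad_reflect <- function(m, r) {
  if (r < 1L) return(m)
  nr <- nrow(m); nc <- ncol(m)
  if (r > nr || r > nc) stop("padding radius exceeds image size")
  ri <- c(r:1, seq_len(nr), nr:(nr - r + 1L))
  ci <- c(r:1, seq_len(nc), nc:(nc - r + 1L))
  m[ri, ci, drop = FALSE]
}

# separable convolution with a symmetric odd-length kernel, reflective borders
conv_sep <- function(img, kernel) {
  k <- length(kernel)
  stopifnot(k %% 2L == 1L)
  r <- (k - 1L) / 2L
  if (r == 0L) return(img * kernel)
  p <- pad_reflect(img, r)
  # stats::filter convolves each column of a matrix
  v <- stats::filter(p, kernel, method = "convolution", sides = 2L)
  v <- v[(r + 1L):(r + nrow(img)), , drop = FALSE]
  v <- stats::filter(t(v), kernel, method = "convolution", sides = 2L)
  t(v)[, (r + 1L):(r + ncol(img)), drop = FALSE]
}

gaussian_kernel <- function(sigma_px) {
  stopifnot(sigma_px > 0)
  r <- max(1L, ceiling(3 * sigma_px))
  x <- (-r):r
  k <- exp(-x^2 / (2 * sigma_px^2))
  k / sum(k)
}

#' Gaussian blur with reflective borders
#'
#' @param img numeric matrix.
#' @param sigma_px standard deviation of the Gaussian kernel in pixels.
#' @return blurred matrix of the same shape.
#' @keywords internal
gaussian_blur <- function(img, sigma_px) {
  conv_sep(img, gaussian_kernel(sigma_px))
}

# local mean over a w x w square window (w odd), reflective borders
box_mean <- function(img, w) {
  w <- as.integer(w)
  stopifnot(w %% 2L == 1L, w >= 1L)
  conv_sep(img, rep(1 / w, w))
}

#' Label 8-connected components of a binary image
#'
#' @param mask logical or 0/1 matrix.
#' @return integer matrix of component labels (0 = background).
#' @keywords internal
label_components <- function(mask) {
  m <- mask > 0
  nr <- nrow(m); nc <- ncol(m)
  lab <- matrix(0L, nr, nc)
  fg <- which(m)
  if (length(fg) == 0L) return(lab)
  idx <- matrix(0L, nr, nc)
  idx[fg] <- seq_along(fg)
  edges <- list()
  # right
  a <- m[, -nc, drop = FALSE] & m[, -1L, drop = FALSE]
  w <- which(a)
  if (length(w)) {
    i <- ((w - 1L) %% nr) + 1L; j <- ((w - 1L) %/% nr) + 1L
    edges[[length(edges) + 1L]] <- cbind(idx[cbind(i, j)], idx[cbind(i, j + 1L)])
  }
  # down
  a <- m[-nr, , drop = FALSE] & m[-1L, , drop = FALSE]
  w <- which(a)
  if (length(w)) {
    i <- ((w - 1L) %% (nr - 1L)) + 1L; j <- ((w - 1L) %/% (nr - 1L)) + 1L
    edges[[length(edges) + 1L]] <- cbind(idx[cbind(i, j)], idx[cbind(i + 1L, j)])
  }
  # down-right diagonal
  a <- m[-nr, -nc, drop = FALSE] & m[-1L, -1L, drop = FALSE]
  w <- which(a)
  if (length(w)) {
    i <- ((w - 1L) %% (nr - 1L)) + 1L; j <- ((w - 1L) %/% (nr - 1L)) + 1L
    edges[[length(edges) + 1L]] <- cbind(idx[cbind(i, j)], idx[cbind(i + 1L, j + 1L)])
  }
  # up-right diagonal
  a <- m[-1L, -nc, drop = FALSE] & m[-nr, -1L, drop = FALSE]
  w <- which(a)
  if (length(w)) {
    i <- ((w - 1L) %% (nr - 1L)) + 1L; j <- ((w - 1L) %/% (nr - 1L)) + 1L
    edges[[length(edges) + 1L]] <- cbind(idx[cbind(i + 1L, j)], idx[cbind(i, j + 1L)])
  }
  if (length(edges)) {
    el <- do.call(rbind, edges)
    g <- igraph::make_graph(edges = as.vector(t(el)), n = length(fg),
                            directed = FALSE)
    memb <- igraph::components(g)$membership
  } else {
    memb <- seq_along(fg)
  }
  lab[fg] <- as.integer(memb)
  lab
}

#' Remove connected components smaller than a pixel area
#' @keywords internal
remove_small_components <- function(mask, min_area_px) {
  lab <- label_components(mask)
  if (max(lab) == 0L) return(mask & FALSE)
  areas <- tabulate(lab[lab > 0L])
  keep <- which(areas >= min_area_px)
  matrix(lab %in% keep, nrow(mask), ncol(mask))
}

# Pearson correlation over jointly finite pixels of two equally shaped images
ncc_images <- function(a, b) {
  ok <- is.finite(a) & is.finite(b)
  if (sum(ok) < 2L) return(-1)
  av <- a[ok]; bv <- b[ok]
  if (stats::sd(av) == 0 || stats::sd(bv) == 0) return(0)
  stats::cor(av, bv)
}

# NCC between reference and moving image under an integer shift of the moving
# image content by (dr, dc); computed over the overlap region only.
ncc_int_shift <- function(ref, mov, dr, dc) {
  nr <- nrow(ref); nc <- ncol(ref)
  r1 <- max(1L, 1L + dr); r2 <- min(nr, nr + dr)
  c1 <- max(1L, 1L + dc); c2 <- min(nc, nc + dc)
  if (r2 - r1 < 4L || c2 - c1 < 4L) return(-1)
  ncc_images(ref[r1:r2, c1:c2, drop = FALSE],
             mov[(r1 - dr):(r2 - dr), (c1 - dc):(c2 - dc), drop = FALSE])
}

#' Bilinear warp of a B-scan under translation plus vertical shear
#'
#' The transform parameters describe the motion applied to the image content:
#' `out(z, x) = in(z - dz - shear_v * (x - 1), x - dx)`. Samples falling
#' outside the input grid are `NA`.
#'
#' @param img numeric matrix (rows = depth, columns = A-scans).
#' @param dx_px,dz_px lateral and axial translation in pixels.
#' @param shear_v vertical shear (axial pixel shift per lateral pixel).
#' @return warped matrix with `NA` outside the source support.
#' @keywords internal
warp_bscan <- function(img, dx_px, dz_px, shear_v = 0) {
  nr <- nrow(img); nc <- ncol(img)
  xi <- rep(seq_len(nc) - dx_px, each = nr)
  zi <- rep.int(seq_len(nr) - dz_px, nc) -
    shear_v * rep(seq_len(nc) - 1L, each = nr)
  ok <- xi >= 1 & xi <= nc & zi >= 1 & zi <= nr
  out <- rep.int(NA_real_, nr * nc)
  if (any(ok)) {
    x1 <- floor(xi[ok]); z1 <- floor(zi[ok])
    fx <- xi[ok] - x1;   fz <- zi[ok] - z1
    x2 <- pmin.int(x1 + 1, nc); z2 <- pmin.int(z1 + 1, nr)
    i11 <- (x1 - 1) * nr + z1; i21 <- (x1 - 1) * nr + z2
    i12 <- (x2 - 1) * nr + z1; i22 <- (x2 - 1) * nr + z2
    out[ok] <- (1 - fx) * ((1 - fz) * img[i11] + fz * img[i21]) +
      fx * ((1 - fz) * img[i12] + fz * img[i22])
  }
  matrix(out, nr, nc)
}

# coarse integer (dr, dc) maximizing the circular cross-correlation of two
# mean-removed images, restricted to |dr|, |dc| <= max_shift. FFT-based;
# used to seed the registration refinements.
xcorr_peak_shift <- function(ref, mov, max_shift = 8L) {
  a <- ref - mean(ref); b <- mov - mean(mov)
  cc <- Re(stats::fft(stats::fft(a) * Conj(stats::fft(b)), inverse = TRUE))
  nr <- nrow(cc); nc <- ncol(cc)
  sh <- function(n) { s <- (-max_shift):max_shift; 1L + (s %% n) }
  sub <- cc[sh(nr), sh(nc), drop = FALSE]
  best <- which(sub == max(sub), arr.ind = TRUE)[1L, ]
  s <- (-max_shift):max_shift
  # cc[i+1, j+1] is large when mov shifted by (-i, -j) matches ref, i.e.
  # when the content of mov must move by (+i, +j)... verify by convention:
  # fft(a)*Conj(fft(b)) peaks at the displacement of b relative to a.
  c(dr = s[best[1L]], dc = s[best[2L]])
}

# integer shift of a 2-D frame with zero fill (used for video registration)
shift_int <- function(img, dr, dc, fill = 0) {
  nr <- nrow(img); nc <- ncol(img)
  out <- matrix(fill, nr, nc)
  r1 <- max(1L, 1L + dr); r2 <- min(nr, nr + dr)
  c1 <- max(1L, 1L + dc); c2 <- min(nc, nc + dc)
  if (r2 >= r1 && c2 >= c1) {
    out[r1:r2, c1:c2] <- img[(r1 - dr):(r2 - dr), (c1 - dc):(c2 - dc)]
  }
  out
}

# 2-D median filter with window w (odd), reflective borders; used to
# regularize detected layer surfaces laterally.
median_filter2 <- function(img, w = 3L) {
  w <- as.integer(w)
  stopifnot(w %% 2L == 1L)
  r <- (w - 1L) / 2L
  if (r == 0L) return(img)
  p <- pad_reflect(img, r)
  out <- img
  nr <- nrow(img); nc <- ncol(img)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      out[i, j] <- stats::median(p[i:(i + 2L * r), j:(j + 2L * r)])
    }
  }
  out
}

# parabolic refinement of a discrete peak location; returns fractional index
refine_peak_parabolic <- function(y, i) {
  n <- length(y)
  if (i <= 1L || i >= n) return(as.numeric(i))
  denom <- y[i - 1L] - 2 * y[i] + y[i + 1L]
  if (denom == 0) return(as.numeric(i))
  i + 0.5 * (y[i - 1L] - y[i + 1L]) / denom
}
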