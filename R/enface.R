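# Layer-surface handling and en-face slab projection. Surfaces are named
# per-(B-scan, A-scan) depth-index maps ordered anatomically from the inner
# limiting membrane down; slabs resolve named boundaries plus micrometre
# offsets into half-open axial pixel ranges [upper, lower).

#' Surface set
#'
#' @param surfaces named list of numeric matrices `[n_bscans x n_ascans]` of
#'   1-based depth pixel indices, ordered from shallow to deep.
#' @param z_spacing_um axial micrometres per depth pixel.
#' @param n_depth total depth pixels of the parent volume (for validation).
#' @return object of class `surface_set`.
#' @export
surface_set <- function(surfaces, z_spacing_um, n_depth = NULL) {
  stopifnot(is.list(surfaces), length(surfaces) >= 1L,
            !is.null(names(surfaces)))
  dims <- unique(lapply(surfaces, dim))
  if (length(dims) != 1L) stop("surface_set: surfaces differ in shape")
  if (length(surfaces) > 1L) {
    for (i in 2L:length(surfaces)) {
      if (any(surfaces[[i]] < surfaces[[i - 1L]]))
        stop(sprintf(
          "surface_set: surface '%s' rises above '%s' somewhere",
          names(surfaces)[i], names(surfaces)[i - 1L]))
    }
  }
  if (!is.null(n_depth)) {
    # lower slab boundaries are exclusive, so n_depth + 1 is a valid index
    rng <- range(unlist(surfaces))
    if (rng[1L] < 1 || rng[2L] > n_depth + 1)
      stop("surface_set: surface indices outside the volume depth")
  }
  structure(list(surfaces = surfaces, z_spacing_um = z_spacing_um),
            class = "surface_set")
}

#' Slab definition
#'
#' @param name slab name (e.g. "SCP", "MCP", "DCP", "FULL").
#' @param upper_ref,lower_ref names of the bounding surfaces (ignored for
#'   "FULL").
#' @param upper_offset_um,lower_offset_um micrometre offsets added to the
#'   bounding surfaces (positive = deeper); converted to pixels rounding
#'   half away from zero.
#' @param projection one of "mean", "max", "sum".
#' @export
slab_definition <- function(name, upper_ref = NULL, lower_ref = NULL,
                            upper_offset_um = 0, lower_offset_um = 0,
                            projection = c("mean", "max", "sum")) {
  projection <- match.arg(projection)
  structure(list(name = name, upper_ref = upper_ref, lower_ref = lower_ref,
                 upper_offset_um = upper_offset_um,
                 lower_offset_um = lower_offset_um,
                 projection = projection),
            class = "slab_definition")
}

#' En-face image
#'
#' @param pixels numeric matrix `[n_bscans x n_ascans]`.
#' @param scale_um_per_px lateral scale.
#' @param slab slab name.
#' @param projection projection statistic used.
#' @export
enface_image <- function(pixels, scale_um_per_px = NA_real_, slab = "FULL",
                         projection = "mean") {
  stopifnot(is.matrix(pixels), all(is.finite(pixels)))
  structure(list(pixels = pixels, scale_um_per_px = scale_um_per_px,
                 slab = slab, projection = projection),
            class = "enface_image")
}

#' @export
print.enface_image <- function(x, ...) {
  cat(sprintf("enface_image [%s, %s]: %d x %d px, %.3g um/px\n",
              x$slab, x$projection, nrow(x$pixels), ncol(x$pixels),
              x$scale_um_per_px))
  invisible(x)
}

#' Detect layer surfaces in a phantom-like structural volume
#'
#' Locates, per A-scan, the `n_surfaces` strongest positive axial-gradient
#' maxima of the (axially smoothed) amplitude profile, median-filters each
#' surface laterally and enforces the shallow-to-deep ordering. Intended for
#' phantom volumes with bright, roughly flat layer interfaces; real-data
#' segmentations are supplied externally as a [surface_set()].
#'
#' @param volume a [structural_volume()] (repeats are averaged) or 3-D array
#'   `[depth, A-scan, B-scan]`.
#' @param n_surfaces number of interfaces to return.
#' @param z_spacing_um axial scale when `volume` is a bare array.
#' @param median_window lateral median filter window (odd).
#' @return a [surface_set()] with surfaces named `surface_1 ... surface_n`
#'   (shallow to deep), each `[n_bscans x n_ascans]`.
#' @export
detect_surfaces_phantom <- function(volume, n_surfaces = 1L,
                                    z_spacing_um = NULL,
                                    median_window = 5L) {
  if (inherits(volume, "structural_volume")) {
    amp <- apply(volume$amplitude, c(1L, 2L, 3L), mean)
    z_spacing_um <- volume$z_spacing_um
  } else {
    amp <- volume
  }
  nz <- dim(amp)[1L]; nx <- dim(amp)[2L]; nb <- dim(amp)[3L]
  # layer-interface detectability: the volume must be far from uniform
  if (stats::sd(amp) < 0.05 * mean(amp) || max(amp) <= 0)
    stop("detect_surfaces_phantom: no detectable interface ",
         "(volume is uniform)")
  sm <- stats::filter(matrix(amp, nz), rep(1 / 3, 3), sides = 2L)
  sm[is.na(sm)] <- matrix(amp, nz)[is.na(sm)]
  g <- apply(matrix(sm, nz), 2L, function(p) c(diff(p), 0))
  surf <- array(NA_real_, dim = c(nb, nx, n_surfaces))
  col <- 0L
  for (b in seq_len(nb)) {
    for (x in seq_len(nx)) {
      col <- col + 1L
      gz <- g[, col]
      # local maxima of the positive gradient
      loc <- which(gz > 0 &
                   gz >= c(-Inf, gz[-nz]) & gz >= c(gz[-1L], -Inf))
      if (length(loc) < n_surfaces)
        stop(sprintf(paste0("detect_surfaces_phantom: only %d interface(s) ",
                            "detectable at B-scan %d, A-scan %d ",
                            "(requested %d)"),
                     length(loc), b, x, n_surfaces))
      top <- loc[order(gz[loc], decreasing = TRUE)][seq_len(n_surfaces)]
      surf[b, x, ] <- sort(top) + 1L  # interface sits at the rise's end
    }
  }
  out <- list()
  for (s in seq_len(n_surfaces)) {
    m <- median_filter2(surf[, , s], median_window)
    out[[paste0("surface_", s)]] <- m
  }
  # enforce ordering after filtering
  if (n_surfaces > 1L) {
    for (s in 2L:n_surfaces)
      out[[s]] <- pmax(out[[s]], out[[s - 1L]])
  }
  surface_set(out, z_spacing_um %||% NA_real_, n_depth = nz)
}

#' Project a slab of a volume into an en-face image
#'
#' Per lateral position, the slab statistic (`mean`, `max` or `sum`) over
#' the half-open axial pixel range `[upper, lower)` resolved from the slab's
#' bounding surfaces plus micrometre offsets (rounded half away from zero).
#' The `FULL` slab spans the whole depth axis; its `sum` projection is the
#' summed volume projection (SVP).
#'
#' @param volume 3-D array `[depth, A-scan, B-scan]`, a
#'   [structural_volume()] (repeats averaged) or the `angio` array of
#'   [fsada_volume()].
#' @param surfaces a [surface_set()] (may be NULL for the FULL slab).
#' @param slab a [slab_definition()].
#' @param scale_um_per_px lateral scale recorded in the output.
#' @return an [enface_image()] of shape `[n_bscans x n_ascans]`.
#' @export
project_slab <- function(volume, surfaces, slab,
                         scale_um_per_px = NA_real_) {
  if (inherits(volume, "structural_volume")) {
    vol <- apply(volume$amplitude, c(1L, 2L, 3L), mean)
  } else vol <- volume
  nz <- dim(vol)[1L]; nx <- dim(vol)[2L]; nb <- dim(vol)[3L]
  if (identical(slab$name, "FULL")) {
    up <- matrix(1L, nb, nx); lo <- matrix(nz + 1L, nb, nx)
  } else {
    zs <- surfaces$z_spacing_um
    up <- surfaces$surfaces[[slab$upper_ref]] +
      round_half_away(slab$upper_offset_um / zs)
    lo <- surfaces$surfaces[[slab$lower_ref]] +
      round_half_away(slab$lower_offset_um / zs)
    up <- pmin(pmax(up, 1), nz)
    lo <- pmin(pmax(lo, 1), nz + 1L)
    bad <- which(up >= lo, arr.ind = TRUE)
    if (nrow(bad))
      stop(sprintf(paste0("project_slab: inverted slab '%s' at B-scan %d, ",
                          "A-scan %d (upper %d >= lower %d)"),
                   slab$name, bad[1L, 1L], bad[1L, 2L],
                   up[bad[1L, , drop = FALSE]], lo[bad[1L, , drop = FALSE]]))
  }
  stat <- switch(slab$projection, mean = mean, max = max, sum = sum)
  out <- matrix(0, nb, nx)
  for (b in seq_len(nb)) {
    sl <- vol[, , b]
    for (x in seq_len(nx)) {
      out[b, x] <- stat(sl[up[b, x]:(lo[b, x] - 1L), x])
    }
  }
  enface_image(out, scale_um_per_px, slab = slab$name,
               projection = slab$projection)
}

#' Surface set from phantom ground truth
#'
#' Builds constant surfaces bracketing each vessel plexus of a phantom (and
#' the tops of the structural layers), so that slabs like
#' `slab_definition("MCP", "MCP_upper", "MCP_lower")` isolate one plexus.
#'
#' @param truth `phantom_truth` from [generate_raw_spectra()].
#' @param pad_px axial pixels added above/below each vessel band.
#' @return a [surface_set()].
#' @export
truth_surface_set <- function(truth, pad_px = 2L) {
  m0 <- truth$vessel_masks[[1L]]
  nb <- nrow(m0); nx <- ncol(m0)
  out <- list()
  depths <- numeric()
  for (nm in names(truth$vessel_rows)) {
    rows <- truth$vessel_rows[[nm]]
    out[[paste0(nm, "_upper")]] <- matrix(min(rows) - pad_px, nb, nx)
    depths[paste0(nm, "_upper")] <- min(rows) - pad_px
    out[[paste0(nm, "_lower")]] <- matrix(max(rows) + pad_px + 1L, nb, nx)
    depths[paste0(nm, "_lower")] <- max(rows) + pad_px + 1L
  }
  out <- out[order(depths)]
  surface_set(out, truth$z_spacing_um)
}

#' Write a surface set to JSON
#' @param surfaces a [surface_set()].
#' @param path output `.json` path.
#' @export
write_surfaces_json <- function(surfaces, path) {
  jsonlite::write_json(
    list(z_spacing_um = surfaces$z_spacing_um,
         surfaces = lapply(surfaces$surfaces, function(m)
           apply(m, 1L, function(r) r, simplify = FALSE))),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a surface set from JSON
#' @param path `.json` path written by [write_surfaces_json()].
#' @export
read_surfaces_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  surfs <- lapply(j$surfaces, function(s) {
    if (is.matrix(s)) s                    # rows already = B-scans
    else if (is.list(s)) t(do.call(cbind, s))
    else matrix(s, nrow = 1L)
  })
  surface_set(surfs, j$z_spacing_um)
}
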