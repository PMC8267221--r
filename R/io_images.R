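# Image, table and configuration I/O. En-face images are written as 16-bit
# grayscale TIFF with a JSON sidecar carrying the intensity scaling and the
# lateral scale in um/px; masks as 0/255 PNG; metrics as CSV with explicit
# column headers; configuration as YAML validated against a small schema.

#' Write an en-face image as 16-bit TIFF
#'
#' Pixel values are mapped linearly onto the 16-bit range using `max_value`
#' (default: image maximum); the mapping and the lateral scale are recorded
#' in a `<path>.json` sidecar so that [read_enface_tiff()] restores the
#' original values.
#'
#' @param image an [enface_image()] or numeric matrix.
#' @param path output `.tif` path.
#' @param max_value intensity mapped to 65535.
#' @return `path`, invisibly.
#' @export
write_enface_tiff <- function(image, path, max_value = NULL) {
  px <- if (inherits(image, "enface_image")) image$pixels else image
  if (is.null(max_value)) max_value <- max(px, 1e-12)
  norm <- pmin(pmax(px / max_value, 0), 1)
  tiff::writeTIFF(norm, path, bits.per.sample = 16L)
  meta <- list(max_value = max_value,
               scale_um_per_px =
                 if (inherits(image, "enface_image")) image$scale_um_per_px
                 else NA,
               slab = if (inherits(image, "enface_image")) image$slab else NA,
               projection =
                 if (inherits(image, "enface_image")) image$projection else NA)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read an en-face image written by [write_enface_tiff()]
#' @param path `.tif` path.
#' @return an [enface_image()].
#' @export
read_enface_tiff <- function(path) {
  px <- tiff::readTIFF(path)
  if (length(dim(px)) == 3L) px <- px[, , 1L]
  sidecar <- paste0(path, ".json")
  meta <- if (file.exists(sidecar)) jsonlite::read_json(sidecar) else list()
  max_value <- if (!is.null(meta$max_value)) meta$max_value else 1
  enface_image(px * max_value,
               scale_um_per_px =
                 if (!is.null(meta$scale_um_per_px) &&
                     !is.na(meta$scale_um_per_px)) meta$scale_um_per_px
                 else NA_real_,
               slab = if (!is.null(meta$slab)) meta$slab else "FULL",
               projection = if (!is.null(meta$projection)) meta$projection
               else "mean")
}

#' Write a binary mask as 0/255 PNG
#' @param mask a [vessel_mask()] or logical/0-1 matrix.
#' @param path output `.png` path.
#' @export
write_mask_png <- function(mask, path) {
  m <- if (inherits(mask, "vessel_mask")) mask$mask else mask
  png::writePNG(matrix(as.numeric(m > 0), nrow(m), ncol(m)), path)
  invisible(path)
}

#' Read a 0/255 PNG mask
#' @param path `.png` path.
#' @param scale_um_per_px lateral scale to attach.
#' @export
read_mask_png <- function(path, scale_um_per_px = NA_real_) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3L) m <- m[, , 1L]
  vessel_mask(m > 0.5, scale_um_per_px)
}

#' Write a metrics table as CSV
#' @param metrics data.frame.
#' @param path output `.csv` path.
#' @export
write_metrics_csv <- function(metrics, path) {
  utils::write.csv(metrics, path, row.names = FALSE)
  invisible(path)
}

#' Validate a configuration list against a simple schema
#'
#' The schema is a named list; each entry may give `type` ("numeric",
#' "integer", "character", "logical", "list"), `required` (default FALSE),
#' `min`/`max` bounds and `length`. Unknown config keys are rejected.
#'
#' @param config named list (e.g. from [read_config()]).
#' @param schema schema description.
#' @return `config`, invisibly; errors name the offending field.
#' @export
validate_config <- function(config, schema) {
  unknown <- setdiff(names(config), names(schema))
  if (length(unknown))
    stop(sprintf("config: unknown field(s): %s",
                 paste(unknown, collapse = ", ")))
  for (k in names(schema)) {
    s <- schema[[k]]
    if (!k %in% names(config)) {
      if (isTRUE(s$required)) stop(sprintf("config: missing field '%s'", k))
      next
    }
    v <- config[[k]]
    ok <- switch(s$type %||% "numeric",
                 numeric = is.numeric(v),
                 integer = is.numeric(v) && all(v == floor(v)),
                 character = is.character(v),
                 logical = is.logical(v),
                 list = is.list(v),
                 TRUE)
    if (!ok) stop(sprintf("config: field '%s' is not of type %s", k, s$type))
    if (!is.null(s$length) && length(v) != s$length)
      stop(sprintf("config: field '%s' must have length %d", k, s$length))
    if (is.numeric(v)) {
      if (!is.null(s$min) && any(v < s$min))
        stop(sprintf("config: field '%s' below minimum %g", k, s$min))
      if (!is.null(s$max) && any(v > s$max))
        stop(sprintf("config: field '%s' above maximum %g", k, s$max))
    }
  }
  invisible(config)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a YAML configuration file
#' @param path `.yaml` path.
#' @param schema optional schema for [validate_config()].
#' @export
read_config <- function(path, schema = NULL) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(schema)) validate_config(cfg, schema)
  cfg
}

.log_levels <- c(debug = 1L, info = 2L, warning = 3L, error = 4L)

#' Set or query the package log level
#' @param level one of "debug", "info", "warning", "error".
#' @export
octa_log_level <- function(level = NULL) {
  if (is.null(level)) return(getOption("sdocta.log_level", "info"))
  level <- match.arg(level, names(.log_levels))
  options(sdocta.log_level = level)
  invisible(level)
}

#' Emit a timestamped log message
#' @param level message level.
#' @param ... passed to [sprintf()].
#' @export
octa_log <- function(level = "info", ...) {
  level <- match.arg(level, names(.log_levels))
  if (.log_levels[[level]] < .log_levels[[octa_log_level()]]) return(invisible())
  message(sprintf("[%s] %s %s", format(Sys.time(), "%H:%M:%S"),
                  toupper(level), sprintf(...)))
  invisible()
}

#' Write a multi-page TIFF stack
#'
#' Pages are the depth slices of a structural or angiographic volume; values
#' are linearly mapped to 16 bits with the mapping stored in a JSON sidecar.
#'
#' @param slices list of matrices or a 3-D array sliced along the third axis.
#' @param path output `.tif` path.
#' @param meta extra metadata stored in the sidecar.
#' @export
write_volume_tiff <- function(slices, path, meta = list()) {
  if (is.array(slices) && length(dim(slices)) == 3L) {
    slices <- lapply(seq_len(dim(slices)[3L]), function(i) slices[, , i])
  }
  mx <- max(vapply(slices, max, 0), 1e-12)
  pages <- lapply(slices, function(s) pmin(pmax(s / mx, 0), 1))
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  jsonlite::write_json(c(list(max_value = mx), meta), paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a multi-page TIFF stack written by [write_volume_tiff()]
#' @param path `.tif` path.
#' @return list with `volume` (3-D array) and `meta`.
#' @export
read_volume_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  sidecar <- paste0(path, ".json")
  meta <- if (file.exists(sidecar)) jsonlite::read_json(sidecar) else list()
  mx <- meta$max_value %||% 1
  vol <- array(0, dim = c(nrow(pages[[1L]]), ncol(pages[[1L]]),
                          length(pages)))
  for (i in seq_along(pages)) vol[, , i] <- pages[[i]] * mx
  list(volume = vol, meta = meta)
}
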