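# Open raw-scan format: a binary file (<name>.bin) of little-endian unsigned
# 16-bit camera samples in C order [repeat, bscan, ascan, spectral sample]
# (spectral sample varies fastest) plus a line-oriented UTF-8 text header
# (<name>.hdr.txt) of "key = value" pairs. 12-bit data are right-aligned in
# the 16-bit words. Unknown header keys are preserved on round-trip.

.hdr_required <- c("n_spectral_samples", "n_ascans_per_bscan", "n_bscans",
                   "n_repeats", "line_rate_hz", "repetition_time_ms",
                   "scan_angle_deg", "wavelength_calibration", "bit_depth")

#' Raw scan header
#'
#' Scan parameters accompanying a raw spectral volume: grid counts, timing,
#' scan geometry and the spectrometer's pixel-to-wavelength calibration.
#'
#' @param n_spectral_samples camera pixels per A-scan (e.g. 2048).
#' @param n_ascans_per_bscan A-scans per B-scan.
#' @param n_bscans B-scan (slow-axis) locations per volume.
#' @param n_repeats frames per BM-scan location; angiography needs >= 2.
#' @param line_rate_hz A-scan rate in Hz (e.g. 129500 for a 130 kHz-class
#'   camera).
#' @param repetition_time_ms interscan interval T_R in milliseconds: the delay
#'   between imaging the same location within a BM-scan. Must be at least the
#'   B-scan acquisition time `n_ascans_per_bscan / line_rate_hz * 1000`.
#' @param scan_angle_deg optical scan angle in degrees (length 1, or 2 for
#'   fast/slow axes).
#' @param wavelength_calibration polynomial coefficients `c0, c1, ...` mapping
#'   spectral pixel index p (0-based) to wavelength in nm:
#'   `lambda(p) = sum(c_j * p^j)`. Must be strictly monotonic over the pixel
#'   range.
#' @param bit_depth bits per camera sample (default 12).
#' @param extra named list of additional key/value pairs preserved on
#'   round-trip.
#' @return an object of class `raw_scan_header`.
#' @export
raw_scan_header <- function(n_spectral_samples, n_ascans_per_bscan, n_bscans,
                            n_repeats, line_rate_hz, repetition_time_ms,
                            scan_angle_deg,
                            wavelength_calibration,
                            bit_depth = 12L, extra = list()) {
  h <- list(n_spectral_samples = as.integer(n_spectral_samples),
            n_ascans_per_bscan = as.integer(n_ascans_per_bscan),
            n_bscans = as.integer(n_bscans),
            n_repeats = as.integer(n_repeats),
            line_rate_hz = as.numeric(line_rate_hz),
            repetition_time_ms = as.numeric(repetition_time_ms),
            scan_angle_deg = as.numeric(scan_angle_deg),
            wavelength_calibration = as.numeric(wavelength_calibration),
            bit_depth = as.integer(bit_depth),
            extra = extra)
  class(h) <- "raw_scan_header"
  validate_raw_scan_header(h)
  h
}

validate_raw_scan_header <- function(h) {
  counts <- c(h$n_spectral_samples, h$n_ascans_per_bscan, h$n_bscans,
              h$n_repeats)
  if (any(!is.finite(counts)) || any(counts < 1L))
    stop("raw_scan_header: all counts must be >= 1")
  if (h$bit_depth < 1L || h$bit_depth > 16L)
    stop("raw_scan_header: bit_depth must be in 1..16")
  if (!is.finite(h$line_rate_hz) || h$line_rate_hz <= 0)
    stop("raw_scan_header: line_rate_hz must be positive")
  bscan_ms <- h$n_ascans_per_bscan / h$line_rate_hz * 1000
  if (h$repetition_time_ms < bscan_ms - 1e-9)
    stop(sprintf(paste0("raw_scan_header: repetition_time_ms (%g) shorter ",
                        "than B-scan acquisition time (%g ms)"),
                 h$repetition_time_ms, bscan_ms))
  lam <- header_wavelengths(h)
  d <- diff(lam)
  if (!(all(d > 0) || all(d < 0)))
    stop("raw_scan_header: wavelength calibration is not strictly monotonic")
  invisible(h)
}

#' Wavelengths (nm) at each spectral pixel of a header
#' @param header a [raw_scan_header()].
#' @return numeric vector of length `n_spectral_samples`.
#' @export
header_wavelengths <- function(header) {
  p <- seq_len(header$n_spectral_samples) - 1
  co <- header$wavelength_calibration
  lam <- numeric(length(p))
  for (j in seq_along(co)) lam <- lam + co[j] * p^(j - 1)
  lam
}

#' @export
print.raw_scan_header <- function(x, ...) {
  cat(sprintf(
    "raw_scan_header: %d samples x %d A-scans x %d B-scans x %d repeats\n",
    x$n_spectral_samples, x$n_ascans_per_bscan, x$n_bscans, x$n_repeats))
  cat(sprintf("  line rate %g Hz, T_R %g ms, scan angle %s deg, %d-bit\n",
              x$line_rate_hz, x$repetition_time_ms,
              paste(x$scan_angle_deg, collapse = " x "), x$bit_depth))
  invisible(x)
}

#' Raw spectral volume
#'
#' Camera counts indexed `[spectral sample, A-scan, B-scan, repeat]` (the
#' first array index varies fastest in memory, matching the C-order
#' `[repeat, bscan, ascan, sample]` layout of the binary file).
#'
#' @param header a [raw_scan_header()].
#' @param samples 4-D integer-valued array with dimensions
#'   `c(n_spectral_samples, n_ascans_per_bscan, n_bscans, n_repeats)`.
#' @return an object of class `raw_spectra_volume`.
#' @export
raw_spectra_volume <- function(header, samples) {
  validate_raw_scan_header(header)
  expected <- c(header$n_spectral_samples, header$n_ascans_per_bscan,
                header$n_bscans, header$n_repeats)
  if (!identical(as.integer(dim(samples)), as.integer(expected)))
    stop(sprintf("raw_spectra_volume: sample array is %s, header declares %s",
                 paste(dim(samples), collapse = "x"),
                 paste(expected, collapse = "x")))
  if (any(samples < 0) || any(samples != floor(samples)))
    stop("raw_spectra_volume: samples must be non-negative integers")
  vmax <- 2^header$bit_depth - 1
  if (max(samples) > vmax)
    stop(sprintf(
      "raw_spectra_volume: sample value %d exceeds %d-bit maximum %d",
      max(samples), header$bit_depth, vmax))
  v <- list(header = header, samples = samples)
  class(v) <- "raw_spectra_volume"
  v
}

#' @export
print.raw_spectra_volume <- function(x, ...) {
  cat("raw_spectra_volume\n")
  print(x$header)
  invisible(x)
}

#' Extract one raw frame
#'
#' @param volume a [raw_spectra_volume()].
#' @param repeat_idx repeat (frame within BM-scan), 1-based.
#' @param bscan_idx B-scan location, 1-based.
#' @return numeric matrix `n_spectral_samples x n_ascans`.
#' @export
get_frame <- function(volume, repeat_idx, bscan_idx) {
  volume$samples[, , bscan_idx, repeat_idx]
}

.fmt_val <- function(v) paste(sprintf("%.17g", as.numeric(v)), collapse = " ")

raw_paths <- function(path) {
  base <- sub("\\.bin$", "", path)
  list(bin = paste0(base, ".bin"), hdr = paste0(base, ".hdr.txt"))
}

#' Write a raw spectral volume
#'
#' Emits `<name>.bin` (little-endian uint16, C order
#' `[repeat, bscan, ascan, sample]`) and `<name>.hdr.txt` ("key = value"
#' lines). Byte-deterministic for identical input.
#'
#' @param volume a valid [raw_spectra_volume()].
#' @param path output path; a `.bin` extension is stripped and re-added.
#' @return the two file paths, invisibly.
#' @export
write_raw_volume <- function(volume, path) {
  if (!inherits(volume, "raw_spectra_volume"))
    volume <- raw_spectra_volume(volume$header, volume$samples)  # re-validate
  p <- raw_paths(path)
  h <- volume$header
  lines <- c(
    sprintf("n_spectral_samples = %d", h$n_spectral_samples),
    sprintf("n_ascans_per_bscan = %d", h$n_ascans_per_bscan),
    sprintf("n_bscans = %d", h$n_bscans),
    sprintf("n_repeats = %d", h$n_repeats),
    sprintf("line_rate_hz = %s", .fmt_val(h$line_rate_hz)),
    sprintf("repetition_time_ms = %s", .fmt_val(h$repetition_time_ms)),
    sprintf("scan_angle_deg = %s", .fmt_val(h$scan_angle_deg)),
    sprintf("wavelength_calibration = %s", .fmt_val(h$wavelength_calibration)),
    sprintf("bit_depth = %d", h$bit_depth))
  if (length(h$extra)) {
    for (k in names(h$extra)) {
      lines <- c(lines, sprintf("%s = %s", k,
                                paste(as.character(h$extra[[k]]),
                                      collapse = " ")))
    }
  }
  con <- file(p$hdr, "wb")  # binary mode: LF endings on every platform
  on.exit(close(con), add = TRUE)
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  bcon <- file(p$bin, "wb")
  on.exit(close(bcon), add = TRUE)
  writeBin(as.integer(volume$samples), bcon, size = 2L, endian = "little")
  invisible(p)
}

parse_header_file <- function(hdr_path) {
  lines <- readLines(hdr_path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  kv <- regmatches(lines, regexec("^\\s*([^=]+?)\\s*=\\s*(.*)$", lines))
  bad <- vapply(kv, length, 1L) != 3L
  if (any(bad))
    stop(sprintf("raw header: cannot parse line(s): %s",
                 paste(lines[bad], collapse = "; ")))
  keys <- vapply(kv, `[`, "", 2L)
  vals <- vapply(kv, `[`, "", 3L)
  names(vals) <- keys
  missing <- setdiff(.hdr_required, keys)
  if (length(missing))
    stop(sprintf("raw header: missing required field(s): %s",
                 paste(missing, collapse = ", ")))
  blank <- keys[!nzchar(trimws(vals))]
  blank <- intersect(blank, .hdr_required)
  if (length(blank))
    stop(sprintf("raw header: blank value for field(s): %s",
                 paste(blank, collapse = ", ")))
  num <- function(k) as.numeric(strsplit(trimws(vals[[k]]), "\\s+")[[1]])
  extra_keys <- setdiff(keys, .hdr_required)
  extra <- lapply(vals[extra_keys], function(v) trimws(v))
  raw_scan_header(
    n_spectral_samples = num("n_spectral_samples"),
    n_ascans_per_bscan = num("n_ascans_per_bscan"),
    n_bscans = num("n_bscans"),
    n_repeats = num("n_repeats"),
    line_rate_hz = num("line_rate_hz"),
    repetition_time_ms = num("repetition_time_ms"),
    scan_angle_deg = num("scan_angle_deg"),
    wavelength_calibration = num("wavelength_calibration"),
    bit_depth = num("bit_depth"),
    extra = extra)
}

#' Read a raw spectral volume
#'
#' Counterpart of [write_raw_volume()]; round-trips bit-exactly.
#'
#' @param path path to the `.bin` file (or its base name).
#' @return a [raw_spectra_volume()].
#' @export
read_raw_volume <- function(path) {
  p <- raw_paths(path)
  if (!file.exists(p$hdr)) stop(sprintf("missing header file: %s", p$hdr))
  if (!file.exists(p$bin)) stop(sprintf("missing binary file: %s", p$bin))
  h <- parse_header_file(p$hdr)
  n <- h$n_spectral_samples * h$n_ascans_per_bscan * h$n_bscans * h$n_repeats
  expected_bytes <- 2 * n
  actual_bytes <- file.size(p$bin)
  if (actual_bytes != expected_bytes)
    stop(sprintf(paste0("raw volume truncated or oversized: header declares ",
                        "%d bytes, file has %d bytes"),
                 expected_bytes, actual_bytes))
  con <- file(p$bin, "rb")
  on.exit(close(con), add = TRUE)
  x <- readBin(con, "integer", n = n, size = 2L, signed = FALSE,
               endian = "little")
  samples <- array(x, dim = c(h$n_spectral_samples, h$n_ascans_per_bscan,
                              h$n_bscans, h$n_repeats))
  raw_spectra_volume(h, samples)
}
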