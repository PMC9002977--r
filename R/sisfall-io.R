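#' Sensor configuration for raw-unit conversion
#'
#' SisFall files store raw integer sensor readings. Conversion to
#' physical units is linear: `value = (2 * range / 2^resolution) * bits`.
#' The defaults match the wide-range sensors of the SisFall device:
#' +/-16 g 13-bit primary accelerometer and +/-2000 deg/s 16-bit
#' gyroscope; the secondary accelerometer (+/-8 g, 14-bit) can be
#' selected instead.
#'
#' @param accelerometer Which accelerometer's columns to use:
#'   `"primary"` (columns 1:3) or `"secondary"` (columns 7:9).
#' @param acc_range_g,acc_resolution_bits Accelerometer full range (g,
#'   one-sided) and ADC resolution in bits.
#' @param gyro_range_dps,gyro_resolution_bits Gyroscope full range
#'   (deg/s) and resolution in bits.
#'
#' @return An object of class `sensor_config`.
#' @export
sensor_config <- function(accelerometer = c("primary", "secondary"),
                          acc_range_g = NULL,
                          acc_resolution_bits = NULL,
                          gyro_range_dps = 2000,
                          gyro_resolution_bits = 16L) {
  accelerometer <- match.arg(accelerometer)
  if (is.null(acc_range_g)) {
    acc_range_g <- if (accelerometer == "primary") 16 else 8
  }
  if (is.null(acc_resolution_bits)) {
    acc_resolution_bits <- if (accelerometer == "primary") 13L else 14L
  }
  stopifnot(acc_range_g > 0, gyro_range_dps > 0,
            acc_resolution_bits >= 8, acc_resolution_bits <= 32,
            gyro_resolution_bits >= 8, gyro_resolution_bits <= 32)
  structure(
    list(accelerometer = accelerometer,
         acc_range_g = acc_range_g,
         acc_resolution_bits = as.integer(acc_resolution_bits),
         gyro_range_dps = gyro_range_dps,
         gyro_resolution_bits = as.integer(gyro_resolution_bits)),
    class = "sensor_config"
  )
}

# Least significant bit size in physical units.
sensor_lsb <- function(range, bits) 2 * range / 2^bits

#' Parse a recording filename
#'
#' SisFall recordings follow the convention
#' `<activity>_<subject>_R<NN>.txt`, e.g. `"F07_SA05_R03.txt"`.
#'
#' @param name Filename (directories are stripped).
#' @param sampling_rate_hz Sampling rate to record in the metadata.
#'
#' @return A one-row tibble with `activity_code`, `subject_id`, `trial`
#'   and `sampling_rate_hz`.
#' @export
parse_filename <- function(name, sampling_rate_hz = 200) {
  base <- basename(name)
  m <- regmatches(base,
                  regexec("^([DF][0-9]{2})_([A-Za-z]{2}[0-9]{2})_R([0-9]+)\\.txt$",
                          base))[[1]]
  if (length(m) == 0) {
    abort(paste0("filename does not follow <code>_<subject>_R<NN>.txt: '",
                 base, "'"))
  }
  tibble(activity_code = m[2], subject_id = m[3],
         trial = as.integer(m[4]), sampling_rate_hz = sampling_rate_hz)
}

#' Parse SisFall-format recording text
#'
#' One sample per line: nine comma-separated integers (primary
#' accelerometer x/y/z, gyroscope x/y/z, secondary accelerometer x/y/z).
#' Blank lines, surrounding whitespace and a trailing semicolon per line
#' are tolerated.
#'
#' @param text Raw file content (single string or character vector of
#'   lines).
#' @param meta One-row metadata tibble as from [parse_filename()].
#'
#' @return A `raw_recording`: list with `meta` and `rows` (n x 9 integer
#'   matrix, row order preserved).
#' @export
parse_sisfall_file <- function(text, meta) {
  lines <- if (length(text) == 1) strsplit(text, "\r?\n")[[1]] else text
  keep <- which(!grepl("^\\s*$", lines))
  if (length(keep) == 0) abort("recording is empty")
  toks <- strsplit(sub(";\\s*$", "", trimws(lines[keep])), "\\s*,\\s*")
  nc <- lengths(toks)
  if (any(nc != 9)) {
    i <- which(nc != 9)[1]
    abort(sprintf("line %d: expected 9 columns, found %d", keep[i], nc[i]))
  }
  flat <- suppressWarnings(as.integer(unlist(toks, use.names = FALSE)))
  if (anyNA(flat)) {
    bad <- which(is.na(flat))[1]
    abort(sprintf("line %d: non-integer token '%s'",
                  keep[(bad - 1) %/% 9 + 1],
                  unlist(toks, use.names = FALSE)[bad]))
  }
  rows <- matrix(flat, ncol = 9, byrow = TRUE)
  colnames(rows) <- c("a1x", "a1y", "a1z", "gx", "gy", "gz",
                      "a2x", "a2y", "a2z")
  structure(list(meta = meta, rows = rows), class = "raw_recording")
}

#' Read one SisFall recording from disk
#'
#' @param path Path to a `<code>_<subject>_R<NN>.txt` file.
#' @inheritParams parse_filename
#' @return A `raw_recording`.
#' @export
read_sisfall <- function(path, sampling_rate_hz = 200) {
  meta <- parse_filename(path, sampling_rate_hz)
  parse_sisfall_file(readLines(path, warn = FALSE), meta)
}

#' Write a recording in SisFall format
#'
#' Inverse of [parse_sisfall_file()]: comma-separated integers, one
#' sample per line, trailing semicolon (the public dataset's dialect).
#'
#' @param rec A `raw_recording`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sisfall <- function(rec, path) {
  stopifnot(inherits(rec, "raw_recording"))
  lines <- paste0(apply(rec$rows, 1, paste, collapse = ","), ";")
  writeLines(lines, path)
  invisible(path)
}

#' Convert raw sensor integers to physical units
#'
#' Selects one accelerometer (see [sensor_config()]) and applies the
#' linear conversion `value = (2 * range / 2^resolution) * bits` to give
#' acceleration in g and angular rate in deg/s. Output channel order is
#' fixed: Ax, Ay, Az, Gx, Gy, Gz.
#'
#' @param rec A `raw_recording`.
#' @param config A [sensor_config()].
#'
#' @return An `imu_signal`: list with `meta` and `samples` (T x 6
#'   numeric matrix).
#' @export
convert_units <- function(rec, config = sensor_config()) {
  stopifnot(inherits(rec, "raw_recording"), inherits(config, "sensor_config"))
  acc_cols <- if (config$accelerometer == "primary") 1:3 else 7:9
  acc <- rec$rows[, acc_cols, drop = FALSE] *
    sensor_lsb(config$acc_range_g, config$acc_resolution_bits)
  gyr <- rec$rows[, 4:6, drop = FALSE] *
    sensor_lsb(config$gyro_range_dps, config$gyro_resolution_bits)
  samples <- cbind(acc, gyr)
  colnames(samples) <- c("ax", "ay", "az", "gx", "gy", "gz")
  structure(list(meta = rec$meta, samples = samples), class = "imu_signal")
}

#' @export
print.raw_recording <- function(x, ...) {
  cat("<raw_recording ", x$meta$activity_code, "_", x$meta$subject_id,
      "_R", x$meta$trial, ": ", nrow(x$rows), " samples @ ",
      x$meta$sampling_rate_hz, " Hz>\n", sep = "")
  invisible(x)
}

#' @export
print.imu_signal <- function(x, ...) {
  cat("<imu_signal ", x$meta$activity_code, ": ", nrow(x$samples),
      " x 6 (g, deg/s)>\n", sep = "")
  invisible(x)
}

#' Read a directory tree of SisFall recordings
#'
#' Recursively collects `*.txt` files following the naming convention
#' (directory-per-subject layouts work out of the box). Files whose
#' names do not match the convention are skipped with a message.
#'
#' @param dir Root directory.
#' @inheritParams parse_filename
#' @return A tibble with columns `file`, `activity_code`, `subject_id`,
#'   `trial` and a `recording` list-column of `raw_recording` objects.
#' @export
read_sisfall_dir <- function(dir, sampling_rate_hz = 200) {
  files <- sort(list.files(dir, pattern = "\\.txt$", recursive = TRUE,
                           full.names = TRUE))
  ok <- grepl("^[DF][0-9]{2}_[A-Za-z]{2}[0-9]{2}_R[0-9]+\\.txt$",
              basename(files))
  if (any(!ok)) {
    inform(paste0("skipping ", sum(!ok),
                  " file(s) not matching the naming convention"))
  }
  files <- files[ok]
  if (length(files) == 0) abort(paste0("no SisFall recordings under ", dir))
  recs <- purrr::map(files, read_sisfall, sampling_rate_hz = sampling_rate_hz)
  meta <- purrr::map_dfr(recs, "meta")
  dplyr::bind_cols(tibble(file = basename(files)), meta,
                   tibble(recording = recs))
}
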