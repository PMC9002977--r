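#' Windowing configuration
#'
#' Recordings are cut into fixed-duration windows before feature
#' extraction: 3 s at 200 Hz by default (window length L = 600
#' samples). Most recordings contribute a single window centred on the
#' peak of the acceleration magnitude; the long continuous
#' walking/jogging recordings (codes D01-D04) are instead cut into
#' consecutive non-overlapping windows.
#'
#' @param duration_s Window duration in seconds.
#' @param fs Sampling rate in Hz; `duration_s * fs` must be a positive
#'   integer (the window length L).
#' @param sliding_codes Activity codes segmented with the non-overlap
#'   sliding scheme.
#'
#' @return An object of class `windowing_config`.
#' @export
windowing_config <- function(duration_s = 3, fs = 200,
                             sliding_codes = c("D01", "D02", "D03", "D04")) {
  L <- duration_s * fs
  if (L <= 0 || abs(L - round(L)) > 1e-9) {
    abort("duration_s * fs must be a positive integer")
  }
  structure(
    list(duration_s = duration_s, fs = fs, length = as.integer(round(L)),
         sliding_codes = sliding_codes),
    class = "windowing_config"
  )
}

#' Acceleration magnitude (SMV)
#'
#' The support magnitude vector at one sample is the root sum of squares
#' of the three acceleration components,
#' `SMV = sqrt(ax^2 + ay^2 + az^2)`. Its maximum over a recording
#' locates the impact (or most dynamic instant) used as window centre.
#'
#' @param ax,ay,az Acceleration components (any consistent unit);
#'   vectorised.
#' @return Non-negative numeric vector.
#' @examples
#' smv(3, 4, 0) # 5
#' @export
smv <- function(ax, ay, az) sqrt(ax^2 + ay^2 + az^2)

#' Index of the SMV peak
#'
#' @param signal An `imu_signal` (or a T x >=3 matrix whose first three
#'   columns are acceleration).
#' @return 1-based index of the maximum per-sample SMV; ties broken by
#'   the earliest index.
#' @export
peak_index <- function(signal) {
  samples <- if (inherits(signal, "imu_signal")) signal$samples else signal
  if (is.null(dim(samples)) || nrow(samples) < 1) {
    abort("signal must have at least one sample")
  }
  s <- smv(samples[, 1], samples[, 2], samples[, 3])
  which.max(s) # first maximum
}

new_window_tbl <- function(samples_list, label, code, subject, trial,
                           start, end, tag = "original") {
  tibble(
    samples = samples_list, label = label, code = code,
    subject = subject, trial = trial,
    start = as.integer(start), end = as.integer(end), tag = tag
  )
}

#' Extract the peak-centred window
#'
#' The window of length L nominally spans `[p - L/2, p + L/2)` around
#' the SMV peak p; when that span leaves the recording it is shifted
#' minimally so that it fits (start clamped to `[1, T - L + 1]`). The
#' result always has exactly L rows and contains the peak sample.
#'
#' @param signal An `imu_signal`.
#' @param config A [windowing_config()].
#' @param label Class label to attach.
#' @return A one-row window tibble (`samples` list-column of L x 6
#'   matrices, `label`, provenance columns `code`/`subject`/`trial`/
#'   `start`/`end`, `tag`).
#' @export
extract_peak_window <- function(signal, config = windowing_config(), label) {
  stopifnot(inherits(signal, "imu_signal"))
  L <- config$length
  T_ <- nrow(signal$samples)
  if (T_ < L) {
    abort(sprintf("recording %s_%s_R%d has %d samples, shorter than one window (%d)",
                  signal$meta$activity_code, signal$meta$subject_id,
                  signal$meta$trial, T_, L))
  }
  p <- peak_index(signal)
  start <- p - L %/% 2L
  start <- max(1L, min(start, T_ - L + 1L))
  end <- start + L - 1L
  new_window_tbl(list(signal$samples[start:end, , drop = FALSE]),
                 label, signal$meta$activity_code, signal$meta$subject_id,
                 signal$meta$trial, start, end)
}

#' Extract consecutive non-overlapping windows
#'
#' Spans rows `[1, L], [L+1, 2L], ...`; a trailing remainder shorter
#' than L is discarded, so a recording shorter than L yields no windows.
#'
#' @inheritParams extract_peak_window
#' @return A window tibble with `floor(T / L)` rows (possibly empty).
#' @export
extract_sliding_windows <- function(signal, config = windowing_config(), label) {
  stopifnot(inherits(signal, "imu_signal"))
  L <- config$length
  T_ <- nrow(signal$samples)
  n <- T_ %/% L
  if (n == 0) {
    return(new_window_tbl(list(), character(), character(), character(),
                          integer(), integer(), integer(), character()))
  }
  starts <- (seq_len(n) - 1L) * L + 1L
  new_window_tbl(
    purrr::map(starts, function(s) signal$samples[s:(s + L - 1L), , drop = FALSE]),
    label, signal$meta$activity_code, signal$meta$subject_id,
    signal$meta$trial, starts, starts + L - 1L
  )
}

#' Window one recording according to its activity code
#'
#' Dispatches to [extract_sliding_windows()] for codes in
#' `config$sliding_codes` and to [extract_peak_window()] otherwise.
#' Codes excluded by the label scheme yield an empty tibble (with a
#' message), never an error, so whole directory sweeps run unattended.
#'
#' @param signal An `imu_signal`.
#' @param scheme A [label_scheme()].
#' @param config A [windowing_config()].
#' @return A window tibble; every row carries the mapped class label.
#' @export
window_recording <- function(signal, scheme, config = windowing_config()) {
  stopifnot(inherits(signal, "imu_signal"))
  code <- signal$meta$activity_code
  label <- map_label(code, scheme)
  if (is.na(label)) {
    inform(paste0("code ", code, " is excluded by the label scheme; skipping"))
    return(new_window_tbl(list(), character(), character(), character(),
                          integer(), integer(), integer(), character()))
  }
  if (code %in% config$sliding_codes) {
    extract_sliding_windows(signal, config, label)
  } else {
    extract_peak_window(signal, config, label)
  }
}

#' Window a whole set of recordings
#'
#' Data-frame-first wrapper: takes the tibble from [read_sisfall_dir()],
#' converts units and windows every recording.
#'
#' @param recordings Tibble with a `recording` list-column of
#'   `raw_recording` objects (as from [read_sisfall_dir()]).
#' @param scheme A [label_scheme()].
#' @param config A [windowing_config()].
#' @param sensor A [sensor_config()].
#' @return A window tibble, one row per extracted window.
#' @export
window_dataset <- function(recordings, scheme,
                           config = windowing_config(),
                           sensor = sensor_config()) {
  stopifnot(is.data.frame(recordings), "recording" %in% names(recordings))
  out <- purrr::map(recordings$recording, function(rec) {
    window_recording(convert_units(rec, sensor), scheme, config)
  })
  dplyr::bind_rows(out)
}
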