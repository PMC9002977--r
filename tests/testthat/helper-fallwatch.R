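# Shared fixture builders (all programmatic, nothing on disk).

toy_meta <- function(code = "F01", subject = "SA01", trial = 1L, fs = 200) {
  tibble::tibble(activity_code = code, subject_id = subject,
                 trial = trial, sampling_rate_hz = fs)
}

toy_signal <- function(samples, code = "F01") {
  structure(list(meta = toy_meta(code), samples = samples),
            class = "imu_signal")
}

# A window tibble with constant-valued windows, one value per window,
# so individual windows are easy to track through transforms.
toy_windows <- function(labels, L = 20L, value = seq_along(labels)) {
  tibble::tibble(
    samples = lapply(value, function(v) matrix(v, L, 6)),
    label = labels, code = "F01", subject = "SA01",
    trial = 1L, start = 1L, end = L, tag = "original"
  )
}

# Two well-separated sinusoid classes for small model fits.
separable_windows <- function(n_per_class = 30L, L = 40L, seed = 42L,
                              classes = c("A", "B")) {
  withr::with_seed(seed, {
    rows <- lapply(seq_len(n_per_class * length(classes)), function(i) {
      cl <- classes[(i - 1) %% length(classes) + 1]
      t <- seq_len(L) / L
      base <- if (cl == classes[1]) sin(2 * pi * 3 * t) else {
        2 * sin(2 * pi * 7 * t)
      }
      m <- matrix(rnorm(L * 6, 0, 0.05), L, 6) + base
      tibble::tibble(samples = list(m), label = cl, code = "F01",
                     subject = "SA01", trial = 1L, start = 1L,
                     end = L, tag = "original")
    })
    dplyr::bind_rows(rows)
  })
}

per_row_smv <- function(samples) {
  sqrt(samples[, 1]^2 + samples[, 2]^2 + samples[, 3]^2)
}

# Independent exhaustive-scan oracle for the peak locator.
brute_force_peak <- function(samples) {
  best <- 1L
  for (i in seq_len(nrow(samples))) {
    if (per_row_smv(samples)[i] > per_row_smv(samples)[best]) best <- i
  }
  best
}
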