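#' Synthetic SisFall-style dataset configuration
#'
#' The generator emulates the file layout, sampling rate, class
#' structure and signal character of waist-worn IMU recordings: a 1 g
#' gravity baseline on one axis, plus an additive class-specific
#' component, plus a Gaussian noise floor, quantised to sensor integers
#' through the inverse of the unit conversion. Walking and jogging get
#' periodic gait oscillation (jogging larger and faster), sitting a
#' smooth postural transition with a transient, standing a quasi-static
#' sway. Falls place exactly one impact transient at a random interior
#' time at least half a window from both ends; its axis and sign encode
#' direction (forward +x, backward -x, lateral +y), its peak amplitude
#' encodes severity, and soft falls additionally get a smaller
#' pre-impact support bump and both severities a post-impact orientation
#' change. The signal model is additive and piecewise-deterministic, not
#' biomechanically realistic: its purpose is to exercise the pipeline.
#'
#' @param subjects Number of subjects (`SA01`, `SA02`, ...).
#' @param fs Sampling rate (Hz).
#' @param duration_long_s Duration of the continuous walking/jogging
#'   recordings (codes D01-D04).
#' @param duration_short_s Duration of all other recordings.
#' @param noise_floor_sd Accelerometer noise floor (g).
#' @param gyro_noise_sd Gyroscope noise floor (deg/s).
#' @param gait_freq_walk_hz,gait_amp_walk_g Walking oscillation.
#' @param gait_freq_jog_hz,gait_amp_jog_g Jogging oscillation (larger
#'   and faster than walking).
#' @param sit_bump_g Transient amplitude of the sitting transition.
#' @param quiescent_amp_g Standing sway amplitude.
#' @param impact_hard_g,impact_soft_g Fall impact peak amplitudes; must
#'   satisfy hard > soft > the largest ADL SMV excursion.
#' @param support_bump_g Pre-impact support bump of soft falls.
#' @param margin_s Minimum distance of the impact from either end (s);
#'   keep it at least half the window duration.
#' @param seed Integer seed; every recording derives its own stream
#'   from it, so generation order does not matter.
#'
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(subjects = 2L, fs = 200,
                             duration_long_s = 100,
                             duration_short_s = 12,
                             noise_floor_sd = 0.01,
                             gyro_noise_sd = 1,
                             gait_freq_walk_hz = 1.8,
                             gait_amp_walk_g = 0.25,
                             gait_freq_jog_hz = 2.8,
                             gait_amp_jog_g = 0.7,
                             sit_bump_g = 1.2,
                             quiescent_amp_g = 0.02,
                             impact_hard_g = 6,
                             impact_soft_g = 3,
                             support_bump_g = 1,
                             margin_s = 1.6,
                             seed = 1L) {
  adl_max_smv <- 1 + max(gait_amp_walk_g, gait_amp_jog_g, sit_bump_g,
                         quiescent_amp_g)
  if (!(impact_hard_g > impact_soft_g && impact_soft_g > adl_max_smv)) {
    abort("need impact_hard_g > impact_soft_g > max ADL SMV amplitude")
  }
  structure(
    list(subjects = as.integer(subjects), fs = fs,
         duration_long_s = duration_long_s,
         duration_short_s = duration_short_s,
         noise_floor_sd = noise_floor_sd, gyro_noise_sd = gyro_noise_sd,
         gait_freq_walk_hz = gait_freq_walk_hz,
         gait_amp_walk_g = gait_amp_walk_g,
         gait_freq_jog_hz = gait_freq_jog_hz,
         gait_amp_jog_g = gait_amp_jog_g,
         sit_bump_g = sit_bump_g, quiescent_amp_g = quiescent_amp_g,
         impact_hard_g = impact_hard_g, impact_soft_g = impact_soft_g,
         support_bump_g = support_bump_g, margin_s = margin_s,
         seed = as.integer(seed)),
    class = "synthetic_config"
  )
}

# Quantise physical values to sensor integers (inverse of
# convert_units); clamps to the signed integer range of the ADC.
quantize_sensor <- function(values, range, bits) {
  lsb <- sensor_lsb(range, bits)
  q <- round(values / lsb)
  lim <- 2^(bits - 1)
  matrix(as.integer(pmin(pmax(q, -lim), lim - 1)),
         nrow(values), ncol(values))
}

gauss_pulse <- function(t, centre, sd) exp(-(t - centre)^2 / (2 * sd^2))

#' Simulate one SisFall-format recording
#'
#' Deterministic given `(code, subject, trial, config$seed)`; the RNG
#' state of the caller is untouched.
#'
#' @param code Activity code covered by the label table.
#' @param subject Subject index (integer) or id string like `"SA01"`.
#' @param trial Trial number.
#' @param config A [synthetic_config()].
#' @return A `raw_recording` with attributes `impact_index` (sample
#'   index of the injected impact, `NA` for non-falls) and `label`
#'   (ten-class label).
#' @export
simulate_recording <- function(code, subject, trial,
                               config = synthetic_config()) {
  scheme <- label_scheme("ten_class")
  label <- map_label(code, scheme)
  if (is.na(label)) abort(paste0("unknown activity code: ", code))
  if (is.numeric(subject)) subject <- sprintf("SA%02d", subject)
  subj_num <- as.integer(sub("^[A-Za-z]+", "", subject))
  code_idx <- match(code, names(scheme$mapping))

  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed((config$seed %% 100003L) * 15077L + code_idx * 4051L +
             subj_num * 257L + as.integer(trial))

  fs <- config$fs
  dur <- if (code %in% c("D01", "D02", "D03", "D04")) {
    config$duration_long_s
  } else {
    config$duration_short_s
  }
  n <- round(dur * fs)
  t <- (seq_len(n) - 1) / fs
  acc <- matrix(0, n, 3) # g; columns x, y, z
  gyr <- matrix(0, n, 3) # deg/s
  acc[, 3] <- 1 # gravity
  impact_index <- NA_integer_

  jitter <- function(x, f = 0.1) x * runif(1, 1 - f, 1 + f)
  if (label %in% c("W", "J")) {
    freq <- jitter(if (label == "W") config$gait_freq_walk_hz else
      config$gait_freq_jog_hz, 0.05)
    amp <- jitter(if (label == "W") config$gait_amp_walk_g else
      config$gait_amp_jog_g)
    phi <- runif(1, 0, 2 * pi)
    acc[, 1] <- acc[, 1] + amp * sin(2 * pi * freq * t + phi)
    acc[, 3] <- acc[, 3] + 0.6 * amp * sin(2 * pi * 2 * freq * t + phi / 2)
    gyr[, 2] <- gyr[, 2] + 80 * amp * sin(2 * pi * freq * t + phi)
  } else if (label == "S") {
    tc <- runif(1, config$margin_s, dur - config$margin_s)
    s_t <- stats::plogis((t - tc) / 0.3) # smooth postural transition
    acc[, 3] <- 1 - 0.5 * s_t        # gravity tilts as the trunk reclines
    acc[, 1] <- acc[, 1] + 0.85 * s_t
    acc[, 1] <- acc[, 1] + jitter(config$sit_bump_g) *
      gauss_pulse(t, tc, 0.1)
    gyr[, 2] <- gyr[, 2] + 80 * gauss_pulse(t, tc, 0.2)
  } else if (label == "SB") {
    amp <- jitter(config$quiescent_amp_g)
    acc[, 1] <- acc[, 1] + amp * sin(2 * pi * 0.3 * t + runif(1, 0, 2 * pi))
  } else {
    # falls: direction from the first letter, severity from the third
    direction <- substr(label, 1, 1)
    hard <- substr(label, 2, 2) == "H"
    axis <- if (direction == "L") 2L else 1L
    sgn <- if (direction == "B") -1 else 1
    ti <- runif(1, config$margin_s, dur - config$margin_s)
    impact_index <- as.integer(round(ti * fs) + 1L)
    peak <- jitter(if (hard) config$impact_hard_g else config$impact_soft_g,
                   0.05)
    pulse <- gauss_pulse(t, ti, 0.05)
    # mild ambulation before the impact
    pre <- t < ti - 0.3
    acc[pre, 1] <- acc[pre, 1] +
      0.15 * sin(2 * pi * 1.5 * t[pre] + runif(1, 0, 2 * pi))
    acc[, axis] <- acc[, axis] + sgn * peak * pulse
    acc[, 3] <- acc[, 3] + 0.4 * peak * pulse / max(peak, 1)
    if (!hard) {
      acc[, axis] <- acc[, axis] + sgn * config$support_bump_g *
        gauss_pulse(t, ti - 0.5, 0.15)
    }
    # post-impact orientation change: lying on the fall side
    post <- stats::plogis((t - ti - 0.3) / 0.1)
    acc[, 3] <- acc[, 3] - 0.8 * post
    acc[, axis] <- acc[, axis] + sgn * 0.9 * post
    gyro_axis <- if (direction == "L") 1L else 2L
    gyr[, gyro_axis] <- gyr[, gyro_axis] +
      sgn * (if (hard) 300 else 150) * gauss_pulse(t, ti, 0.08)
  }

  acc <- acc + matrix(rnorm(3 * n, 0, config$noise_floor_sd), n, 3)
  gyr <- gyr + matrix(rnorm(3 * n, 0, config$gyro_noise_sd), n, 3)

  primary <- sensor_config("primary")
  secondary <- sensor_config("secondary")
  rows <- cbind(
    quantize_sensor(acc, primary$acc_range_g, primary$acc_resolution_bits),
    quantize_sensor(gyr, primary$gyro_range_dps, primary$gyro_resolution_bits),
    quantize_sensor(acc, secondary$acc_range_g, secondary$acc_resolution_bits)
  )
  colnames(rows) <- c("a1x", "a1y", "a1z", "gx", "gy", "gz",
                      "a2x", "a2y", "a2z")
  meta <- tibble(activity_code = code, subject_id = subject,
                 trial = as.integer(trial), sampling_rate_hz = fs)
  rec <- structure(list(meta = meta, rows = rows), class = "raw_recording")
  attr(rec, "impact_index") <- impact_index
  attr(rec, "label") <- label
  rec
}

#' Simulate a full SisFall-style dataset on disk
#'
#' Writes a directory-per-subject tree of SisFall-named recordings
#' covering every code of the label table with the standard per-code
#' trial counts (one long recording for D01-D04, five trials
#' otherwise), plus a `manifest.csv` listing every recording with its
#' ground-truth class and injected impact index (-1 for non-falls).
#'
#' @param config A [synthetic_config()].
#' @param dir Output directory (created if missing).
#' @return The manifest tibble (`file`, `code`, `subject`, `trial`,
#'   `label`, `impact_index`), invisibly.
#' @export
simulate_dataset <- function(config = synthetic_config(), dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  codes <- sisfall_code_table()
  rows <- list()
  for (s in seq_len(config$subjects)) {
    subject <- sprintf("SA%02d", s)
    subj_dir <- file.path(dir, subject)
    if (!dir.exists(subj_dir)) dir.create(subj_dir)
    for (i in seq_len(nrow(codes))) {
      for (trial in seq_len(codes$trials[i])) {
        rec <- simulate_recording(codes$code[i], subject, trial, config)
        fname <- sprintf("%s_%s_R%02d.txt", codes$code[i], subject, trial)
        write_sisfall(rec, file.path(subj_dir, fname))
        rows[[length(rows) + 1]] <- tibble(
          file = file.path(subject, fname),
          code = codes$code[i], subject = subject, trial = trial,
          label = attr(rec, "label"),
          impact_index = ifelse(is.na(attr(rec, "impact_index")), -1L,
                                attr(rec, "impact_index"))
        )
      }
    }
  }
  manifest <- dplyr::bind_rows(rows)
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}
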