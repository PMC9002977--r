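#' Augmentation configuration
#'
#' The relabelled classes are imbalanced: the standing ADL and all six
#' fall classes have far fewer windows than walking/jogging/sitting.
#' Each training window of those minority classes is expanded with three
#' augmented variants: additive white Gaussian noise (simulating
#' measurement noise), a single uniform amplitude scale (simulating
#' sensor fixation and physique differences) and
#' upsample-then-downsample resampling (simulating sampling
#' inconsistencies).
#'
#' @param noise_sd Standard deviation of the additive Gaussian noise, in
#'   the converted signal units (g / deg/s). Default 0.01.
#' @param scale_low,scale_high Bounds of the uniform scale factor.
#'   Defaults 0.8 and 1.2.
#' @param resample_factor Integer upsampling factor used for the
#'   resampling transform. Default 10.
#' @param minority_classes Labels receiving augmentation.
#' @param seed Integer seed making [augment_minority()] reproducible.
#'
#' @return An object of class `augmentation_config`.
#' @export
augmentation_config <- function(noise_sd = 0.01,
                                scale_low = 0.8, scale_high = 1.2,
                                resample_factor = 10L,
                                minority_classes = c("SB", "FHF", "FSF",
                                                     "BHF", "BSF", "LHF",
                                                     "LSF"),
                                seed = 1L) {
  stopifnot(noise_sd >= 0, scale_low > 0, scale_low <= scale_high,
            resample_factor >= 2)
  structure(
    list(noise_sd = noise_sd, scale_low = scale_low,
         scale_high = scale_high,
         resample_factor = as.integer(resample_factor),
         minority_classes = minority_classes, seed = as.integer(seed)),
    class = "augmentation_config"
  )
}

#' Augmentation transforms
#'
#' Low-level transforms on an L x 6 window matrix. `aug_noise()` adds
#' i.i.d. zero-mean Gaussian noise to every sample of every channel;
#' `aug_scale()` multiplies the whole window by one scalar drawn from
#' Uniform(lo, hi) (a single factor, preserving inter-axis geometry);
#' `aug_resample()` upsamples each channel by linear interpolation and
#' decimates by the same factor, returning exactly L rows
#' (deterministic). The two stochastic transforms use the current R RNG
#' state.
#'
#' @param samples L x 6 numeric matrix.
#' @param sd Noise standard deviation (signal units).
#' @param lo,hi Uniform scale bounds.
#' @param factor Integer resampling factor (>= 2).
#' @return A matrix of the same dimensions.
#' @name augmentation-transforms
NULL

#' @rdname augmentation-transforms
#' @export
aug_noise <- function(samples, sd) {
  stopifnot(sd >= 0)
  if (sd == 0) return(samples)
  samples + matrix(rnorm(length(samples), 0, sd),
                   nrow(samples), ncol(samples))
}

#' @rdname augmentation-transforms
#' @export
aug_scale <- function(samples, lo = 0.8, hi = 1.2) {
  stopifnot(lo > 0, lo <= hi)
  samples * runif(1, lo, hi)
}

#' @rdname augmentation-transforms
#' @export
aug_resample <- function(samples, factor = 10L) {
  stopifnot(factor >= 2)
  L <- nrow(samples)
  # positions of the original samples on the upsampled grid
  up_t <- seq_len((L - 1L) * factor + 1L)
  orig_t <- (seq_len(L) - 1L) * factor + 1L
  out <- samples
  keep <- seq(1L, length(up_t), by = factor) # decimate back to L samples
  for (ch in seq_len(ncol(samples))) {
    up <- approx(orig_t, samples[, ch], xout = up_t)$y
    out[, ch] <- up[keep]
  }
  out
}

#' Augment minority-class windows
#'
#' Returns all input windows (unchanged, in input order) followed by,
#' for each window whose label is in `config$minority_classes`, three
#' augmented variants tagged `noise`, `scale` and `resample`. The output
#' is fully reproducible from `config$seed`; changing the seed changes
#' only the noise and scale variants. Intended for the *training* split
#' only -- validation and test windows are never augmented.
#'
#' @param windows A window tibble (see [window_recording()]).
#' @param config An [augmentation_config()].
#' @return A window tibble with
#'   `nrow(windows) + 3 * (# minority windows)` rows.
#' @export
augment_minority <- function(windows, config = augmentation_config()) {
  stopifnot(is.data.frame(windows), inherits(config, "augmentation_config"))
  if (nrow(windows) == 0) return(windows)
  is_min <- windows$label %in% config$minority_classes
  if (!any(is_min)) return(windows)
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(config$seed)
  aug <- purrr::map(which(is_min), function(i) {
    w <- windows[i, ]
    v <- dplyr::bind_rows(w, w, w)
    v$tag <- c("noise", "scale", "resample")
    v$samples <- list(
      aug_noise(w$samples[[1]], config$noise_sd),
      aug_scale(w$samples[[1]], config$scale_low, config$scale_high),
      aug_resample(w$samples[[1]], config$resample_factor)
    )
    v
  })
  dplyr::bind_rows(windows, dplyr::bind_rows(aug))
}
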