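# Gait and tapping feature extraction: time-domain magnitude/variability
# statistics, FFT-domain spectral summaries of the acceleration-magnitude
# series, and tap-event dexterity/consistency measures.

#' Per-sample total acceleration magnitude
#'
#' @param trace an `accel_trace`.
#' @return numeric vector `sqrt(x^2 + y^2 + z^2)`.
#' @export
magnitude_series <- function(trace) {
  sqrt(trace$x^2 + trace$y^2 + trace$z^2)
}

#' Time-domain acceleration statistics
#'
#' Root mean square and population standard deviation per axis and of the
#' total-magnitude series.
#'
#' @param trace an `accel_trace`.
#' @return named numeric vector: `rms_x`, `rms_y`, `rms_z`, `rms_total`,
#'   `std_x`, `std_y`, `std_z`, `std_total`.
#' @export
time_domain_stats <- function(trace) {
  mag <- magnitude_series(trace)
  c(rms_x = rms(trace$x), rms_y = rms(trace$y), rms_z = rms(trace$z),
    rms_total = rms(mag),
    std_x = pop_sd(trace$x), std_y = pop_sd(trace$y), std_z = pop_sd(trace$z),
    std_total = pop_sd(mag))
}

#' Spectral summary of a uniformly sampled series
#'
#' One-sided amplitude spectrum with the DC bin excluded (the gravity
#' offset dominates raw accelerometer magnitude and carries no movement
#' information).  Dominant frequency is the argmax bin with parabolic
#' refinement disabled (bin resolution is the stated tolerance downstream);
#' the spectral centroid is the amplitude-weighted mean frequency, the mean
#' frequency is the power-weighted (A^2) mean, and the spread is the
#' amplitude-weighted standard deviation about the centroid.
#'
#' @param series numeric vector, length >= 8, finite.
#' @param sample_rate_hz sampling rate of `series`.
#' @param window `"none"` (default) or `"hann"`.
#' @return named numeric vector `dominant_frequency_hz`,
#'   `mean_frequency_hz`, `spectral_centroid_hz`, `spectral_spread_hz`,
#'   plus attribute `degenerate` (TRUE when the spectrum is empty after DC
#'   removal; all fields then 0).
#' @export
spectrum_features <- function(series, sample_rate_hz,
                              window = c("none", "hann")) {
  window <- match.arg(window)
  n <- length(series)
  if (n < 8L) stop("spectrum_features needs at least 8 samples", call. = FALSE)
  if (!all(is.finite(series))) stop("series must be finite", call. = FALSE)
  x <- series - mean(series)
  if (window == "hann") x <- x * hann_window(n)
  sp <- fft(x)
  half <- seq(2L, floor(n / 2) + 1L)          # one-sided, DC excluded
  amp <- Mod(sp[half])
  freqs <- (half - 1L) * sample_rate_hz / n
  tot <- sum(amp)
  if (tot < 1e-12 * n) {
    out <- c(dominant_frequency_hz = 0, mean_frequency_hz = 0,
             spectral_centroid_hz = 0, spectral_spread_hz = 0)
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  centroid <- sum(freqs * amp) / tot
  meanfreq <- sum(freqs * amp^2) / sum(amp^2)
  spread <- sqrt(sum((freqs - centroid)^2 * amp) / tot)
  out <- c(dominant_frequency_hz = freqs[which.max(amp)],
           mean_frequency_hz = meanfreq,
           spectral_centroid_hz = centroid,
           spectral_spread_hz = spread)
  attr(out, "degenerate") <- FALSE
  out
}

#' Tap-event dexterity and consistency features
#'
#' Counts per button, total taps, number of consecutive same-button
#' repeats (failure to alternate), and tapping consistency as the
#' population standard deviation of successive inter-tap intervals.
#'
#' @param taps a `tap_events` series.
#' @return named numeric vector `taps_left`, `taps_right`, `taps_total`,
#'   `taps_repeated`, `tap_consistency_s`; attribute `empty` when the
#'   series has no events (all zeros).
#' @export
tap_event_features <- function(taps) {
  n <- length(taps$times)
  if (n == 0L) {
    out <- c(taps_left = 0, taps_right = 0, taps_total = 0,
             taps_repeated = 0, tap_consistency_s = 0)
    attr(out, "empty") <- TRUE
    return(out)
  }
  left <- sum(taps$buttons == "left")
  repeated <- if (n >= 2L) sum(taps$buttons[-1L] == taps$buttons[-n]) else 0L
  consistency <- if (n >= 3L) pop_sd(diff(taps$times)) else 0
  out <- c(taps_left = left, taps_right = n - left, taps_total = n,
           taps_repeated = repeated, tap_consistency_s = consistency)
  attr(out, "empty") <- FALSE
  out
}

#' Gait feature block (12 features)
#'
#' Time-domain statistics plus the spectral summary of the magnitude
#' series, named with a `gait_` prefix.
#'
#' @param trace a gait `accel_trace`.
#' @return named numeric vector of 12 features.
#' @export
gait_feature_block <- function(trace) {
  td <- time_domain_stats(trace)
  mag <- magnitude_series(trace)
  sp <- if (length(mag) >= 8L) {
    spectrum_features(mag, trace$sample_rate_hz)
  } else {
    s <- c(dominant_frequency_hz = 0, mean_frequency_hz = 0,
           spectral_centroid_hz = 0, spectral_spread_hz = 0)
    attr(s, "degenerate") <- TRUE
    s
  }
  out <- c(td, sp)
  names(out) <- paste0("gait_", names(out))
  attr(out, "degenerate") <- isTRUE(attr(sp, "degenerate"))
  out
}

#' Tapping feature block (17 features)
#'
#' Tap-event features plus time-domain and spectral features of the
#' accelerometer trace recorded during the 20 s tapping test, named with a
#' `tap_` prefix.  A trace too short for a spectrum yields zeroed,
#' degenerate-flagged spectral fields while event features are still
#' computed.
#'
#' @param taps a `tap_events` series.
#' @param trace the tapping-phase `accel_trace`.
#' @return named numeric vector of 17 features.
#' @export
tapping_feature_block <- function(taps, trace) {
  ev <- tap_event_features(taps)
  td <- time_domain_stats(trace)
  mag <- magnitude_series(trace)
  sp <- if (length(mag) >= 8L) {
    spectrum_features(mag, trace$sample_rate_hz)
  } else {
    s <- c(dominant_frequency_hz = 0, mean_frequency_hz = 0,
           spectral_centroid_hz = 0, spectral_spread_hz = 0)
    attr(s, "degenerate") <- TRUE
    s
  }
  out <- c(ev, td, sp)
  names(out) <- paste0("tap_", names(out))
  attr(out, "degenerate") <- isTRUE(attr(sp, "degenerate"))
  attr(out, "empty_taps") <- isTRUE(attr(ev, "empty"))
  out
}
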