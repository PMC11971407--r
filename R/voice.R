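# Sustained-phonation acoustic features: pitch and volume statistics,
# frame-level signal descriptors, breathiness measures (HNR, smoothed
# cepstral peak prominence, glottal-to-noise excitation ratio, harmonic
# difference, high-frequency noise fraction, shimmer, band-level PSD
# difference), the configurable Acoustic Breathiness Index, and
# PCA-reduced MFCC summaries.

#' Slice a clip into overlapping frames
#'
#' @param clip an `audio_clip`.
#' @param frame_length_s frame length in seconds (default 0.040).
#' @param hop_s hop between frame starts (default 0.010).
#' @return object of class `frame_grid`: raw (unwindowed) frames as an
#'   L x n_frames matrix, the Hann window used for spectral descriptors,
#'   and the grid parameters.  Number of frames is
#'   `floor((N - L) / H) + 1`.
#' @export
frame_signal <- function(clip, frame_length_s = 0.040, hop_s = 0.010) {
  fs <- clip$sample_rate_hz
  L <- round(frame_length_s * fs)
  H <- max(1L, round(hop_s * fs))
  N <- length(clip$samples)
  if (N < L) stop("clip shorter than one frame", call. = FALSE)
  n_frames <- floor((N - L) / H) + 1L
  starts <- (seq_len(n_frames) - 1L) * H
  idx <- outer(seq_len(L), starts, `+`)
  structure(list(
    frames = matrix(clip$samples[idx], nrow = L),
    window = hann_window(L),
    frame_length_s = frame_length_s, hop_s = hop_s,
    sample_rate_hz = fs, n_frames = n_frames
  ), class = "frame_grid")
}

# Normalized autocorrelation per frame at lags 1..max_lag, bias-corrected
# by the running energies of the two overlapping segments, so a perfectly
# periodic frame scores ~1 at its pitch lag regardless of lag.
frame_norm_autocorr <- function(grid, max_lag) {
  fr <- grid$frames
  fr <- sweep(fr, 2L, colMeans(fr))
  L <- nrow(fr)
  nfft <- next_pow2(2L * L)
  padded <- rbind(fr, matrix(0, nfft - L, ncol(fr)))
  sp <- mvfft(padded)
  ac <- Re(mvfft(sp * Conj(sp), inverse = TRUE)) / nfft
  ac <- ac[seq_len(max_lag + 1L), , drop = FALSE]
  csum <- apply(rbind(0, fr^2), 2L, cumsum)   # csum[k+1,] = sum of first k squares
  tot <- csum[L + 1L, ]
  lags <- seq_len(max_lag)
  e_head <- csum[L - lags + 1L, , drop = FALSE]         # energy of x[1..L-l]
  e_tail <- matrix(tot, max_lag, ncol(fr), byrow = TRUE) -
    csum[lags + 1L, , drop = FALSE]                     # energy of x[l+1..L]
  den <- sqrt(pmax(e_head * e_tail, .Machine$double.eps))
  r <- ac[-1L, , drop = FALSE] / den
  r[!is.finite(r)] <- 0
  r
}

#' Autocorrelation pitch track
#'
#' Per-frame fundamental frequency from the normalized autocorrelation
#' peak within the search band, refined by parabolic interpolation.
#' Frames whose normalized peak falls below `voicing_threshold` are marked
#' unvoiced.
#'
#' @param grid a `frame_grid`.
#' @param f_min,f_max pitch search range in Hz (defaults 50-500).
#' @param voicing_threshold minimum normalized autocorrelation for a frame
#'   to count as voiced (default 0.3).
#' @return object of class `pitch_track`: `f0_hz` (NA when unvoiced),
#'   `voiced`, `strength` (peak normalized autocorrelation),
#'   `pitch_mean_hz` and `pitch_std_hz` over voiced frames (NA and
#'   `unvoiced_clip = TRUE` when no frame is voiced).
#' @export
pitch_track <- function(grid, f_min = 50, f_max = 500,
                        voicing_threshold = 0.3) {
  fs <- grid$sample_rate_hz
  lag_min <- max(2L, floor(fs / f_max))
  lag_max <- min(nrow(grid$frames) - 1L, ceiling(fs / f_min))
  if (lag_max <= lag_min) stop("frame too short for the pitch search range", call. = FALSE)
  r <- frame_norm_autocorr(grid, lag_max)
  band <- seq(lag_min, lag_max)
  f0 <- rep(NA_real_, grid$n_frames)
  strength <- numeric(grid$n_frames)
  for (j in seq_len(grid$n_frames)) {
    rj <- r[, j]
    rb <- rj[band]
    mx <- max(rb)
    # octave bias: subharmonic lags (2 T0, 3 T0, ...) correlate almost as
    # well as the true period, so take the smallest lag whose local peak
    # is within 10% of the global maximum
    k <- length(rb)
    is_peak <- rb >= c(-Inf, rb[-k]) & rb >= c(rb[-1L], -Inf)
    cand <- which(is_peak & rb >= 0.9 * mx)
    i <- band[if (length(cand)) cand[1L] else which.max(rb)]
    pk <- parabolic_peak(rj, i)
    strength[j] <- min(1, pk$height)
    if (pk$height >= voicing_threshold) f0[j] <- fs / (i + pk$offset)
  }
  voiced <- !is.na(f0)
  structure(list(
    f0_hz = f0, voiced = voiced, strength = strength,
    pitch_mean_hz = if (any(voiced)) mean(f0[voiced]) else NA_real_,
    pitch_std_hz = if (any(voiced)) pop_sd(f0[voiced]) else NA_real_,
    unvoiced_clip = !any(voiced)
  ), class = "pitch_track")
}

#' Frame-level signal descriptors
#'
#' Zero-crossing rate (sign changes per sample), RMS volume, and spectral
#' centroid / bandwidth / rolloff(85%) of the Hann-windowed magnitude
#' spectrum (DC excluded), each aggregated as mean and population standard
#' deviation over frames.  Silent frames contribute zeros.
#'
#' @param grid a `frame_grid`.
#' @param rolloff_quantile fraction of spectral energy below the rolloff
#'   frequency (default 0.85).
#' @return named numeric vector: `zcr_mean`, `zcr_std`, `volume_mean`,
#'   `volume_std`, `spectral_centroid_mean_hz`, `spectral_centroid_std_hz`,
#'   `spectral_bandwidth_mean_hz`, `spectral_bandwidth_std_hz`,
#'   `spectral_rolloff_mean_hz`, `spectral_rolloff_std_hz`.
#' @export
frame_descriptors <- function(grid, rolloff_quantile = 0.85) {
  fr <- grid$frames
  L <- nrow(fr); fs <- grid$sample_rate_hz
  zcr <- colSums(abs(diff(sign(fr))) > 0) / (L - 1L)
  vol <- sqrt(colMeans(fr^2))

  nfft <- next_pow2(L)
  wfr <- fr * grid$window
  sp <- mvfft(rbind(wfr, matrix(0, nfft - L, ncol(fr))))
  half <- seq(2L, nfft / 2 + 1L)
  amp <- Mod(sp[half, , drop = FALSE])
  freqs <- (half - 1L) * fs / nfft
  tot <- colSums(amp)
  silent <- tot < 1e-12
  tot[silent] <- 1
  fmat <- matrix(freqs, length(freqs), ncol(amp))
  centroid <- colSums(freqs * amp) / tot
  cmat <- matrix(centroid, length(freqs), ncol(amp), byrow = TRUE)
  bandwidth <- sqrt(colSums((fmat - cmat)^2 * amp) / tot)
  energy <- amp^2
  etot <- colSums(energy); etot[etot < 1e-24] <- 1
  cum <- apply(energy, 2L, cumsum)
  roll_idx <- vapply(seq_len(ncol(cum)), function(j) {
    which(cum[, j] >= rolloff_quantile * etot[j])[1L]
  }, integer(1))
  rolloff <- freqs[roll_idx]
  centroid[silent] <- 0; bandwidth[silent] <- 0; rolloff[silent] <- 0

  c(zcr_mean = mean(zcr), zcr_std = pop_sd(zcr),
    volume_mean = mean(vol), volume_std = pop_sd(vol),
    spectral_centroid_mean_hz = mean(centroid),
    spectral_centroid_std_hz = pop_sd(centroid),
    spectral_bandwidth_mean_hz = mean(bandwidth),
    spectral_bandwidth_std_hz = pop_sd(bandwidth),
    spectral_rolloff_mean_hz = mean(rolloff),
    spectral_rolloff_std_hz = pop_sd(rolloff))
}

# Locate one waveform peak per glottal cycle, walking forward one median
# period at a time.  Returns sample indices of cycle peaks.
cycle_peaks <- function(samples, fs, f0_median) {
  T0 <- fs / f0_median
  n <- length(samples)
  peaks <- integer(0)
  lo <- 1L
  hi <- min(n, ceiling(1.5 * T0))
  while (lo < n) {
    seg <- samples[lo:hi]
    p <- lo + which.max(seg) - 1L
    peaks <- c(peaks, p)
    lo <- p + max(2L, floor(0.5 * T0))
    hi <- min(n, p + ceiling(1.5 * T0))
    if (lo >= hi) break
  }
  peaks
}

#' Shimmer in decibels
#'
#' Mean absolute dB ratio of consecutive cycle peak amplitudes, with cycle
#' peaks located one per pitch period from the mean tracked f0.
#'
#' @param clip an `audio_clip`.
#' @param pitch a `pitch_track` for the clip.
#' @return scalar dB value; NA for an unvoiced clip or fewer than 3
#'   detected cycles.
#' @export
shimmer_db <- function(clip, pitch) {
  if (isTRUE(pitch$unvoiced_clip)) return(NA_real_)
  f0 <- mean(pitch$f0_hz[pitch$voiced])
  fs <- clip$sample_rate_hz
  s <- clip$samples
  n <- length(s)
  # low-pass to the first few harmonics before peak picking: a sharp
  # pulse-like peak falls between samples and the quantization error
  # would read as shimmer; the per-cycle amplitude factor is common to
  # all harmonics so the filtered peak ratios are unchanged
  fc <- min(5.5 * f0, 0.45 * fs)
  sp <- fft(s)
  fbin <- (seq_len(n) - 1L) * fs / n
  sp[fbin > fc & fbin < fs - fc] <- 0
  sf <- Re(fft(sp, inverse = TRUE)) / n
  pk <- cycle_peaks(sf, fs, f0)
  amps <- vapply(pk, function(i) parabolic_peak(sf, i)$height, numeric(1))
  amps <- amps[amps > 0]
  if (length(amps) < 3L) return(NA_real_)
  mean(abs(20 * log10(amps[-1L] / amps[-length(amps)])))
}

#' Harmonics-to-noise ratio in dB
#'
#' Autocorrelation method: for each voiced frame the normalized
#' autocorrelation at the pitch lag estimates the periodic energy
#' fraction r, and `HNR = 10 log10(r / (1 - r))`, capped at +40 dB;
#' the clip value is the mean over voiced frames.
#'
#' @param grid a `frame_grid`.
#' @param pitch a `pitch_track` computed on the same grid.
#' @param cap_db upper cap (default 40).
#' @return scalar dB value; NA for an unvoiced clip.
#' @export
hnr_db <- function(grid, pitch, cap_db = 40) {
  if (isTRUE(pitch$unvoiced_clip)) return(NA_real_)
  r <- pmin(pitch$strength[pitch$voiced], 1 - 1e-6)
  r <- pmax(r, 1e-6)
  mean(pmin(10 * log10(r / (1 - r)), cap_db))
}

# centered moving average along columns, edges kept unsmoothed
smooth_cols <- function(m, k) {
  if (k <= 1L) return(m)
  kern <- rep(1 / k, k)
  apply(m, 2L, function(v) {
    f <- as.numeric(stats::filter(v, kern, sides = 2))
    f[is.na(f)] <- v[is.na(f)]
    f
  })
}

#' Smoothed cepstral peak prominence (CPPS) in dB
#'
#' Frame log-magnitude spectra (dB) are transformed to power cepstra,
#' smoothed across time and quefrency and expressed in dB; the peak in
#' the pitch-range quefrency band (1/f_max .. 1/f_min seconds) is
#' measured against the linear regression of the dB cepstrum over that
#' band.  Amplitude scaling only shifts the zero-quefrency bin, so CPPS
#' is gain-invariant.
#'
#' @param clip an `audio_clip`.
#' @param frame_length_s,hop_s analysis grid (defaults 0.040 / 0.010).
#' @param f_min,f_max quefrency search band expressed as a pitch range.
#' @param time_smooth,quef_smooth moving-average spans (frames / bins).
#' @return scalar dB value.
#' @export
cpp_smoothed_db <- function(clip, frame_length_s = 0.040, hop_s = 0.010,
                            f_min = 50, f_max = 500,
                            time_smooth = 10L, quef_smooth = 10L) {
  grid <- frame_signal(clip, frame_length_s, hop_s)
  fs <- grid$sample_rate_hz
  L <- nrow(grid$frames)
  nfft <- next_pow2(L)
  wfr <- grid$frames * grid$window
  sp <- mvfft(rbind(wfr, matrix(0, nfft - L, ncol(wfr))))
  logmag <- 20 * log10(Mod(sp) + 1e-12)
  # power cepstrum, smoothed, then expressed in dB so the peak prominence
  # is on the conventional decibel scale
  ceps <- Mod(mvfft(logmag, inverse = TRUE) / nfft)^2
  ceps <- t(smooth_cols(t(ceps), time_smooth))   # across time
  ceps <- smooth_cols(ceps, quef_smooth)         # across quefrency
  ceps <- 10 * log10(ceps + 1e-20)

  q_lo <- max(3L, floor(fs / f_max))
  q_hi <- min(nfft / 2, ceiling(fs / f_min))
  reg_band <- seq(q_lo, q_hi)
  X <- cbind(1, reg_band)
  cpp <- vapply(seq_len(ncol(ceps)), function(j) {
    cj <- ceps[reg_band, j]
    i <- which.max(cj)
    beta <- stats::lm.fit(X, cj)$coefficients
    cj[i] - (beta[1L] + beta[2L] * reg_band[i])
  }, numeric(1))
  mean(cpp)
}

#' Glottal-to-noise excitation ratio
#'
#' The clip is band-limited and resampled to 10 kHz; Hilbert envelopes of
#' 3 kHz-wide bands placed every 500 Hz are correlated, and per 0.5 s
#' segment the maximum correlation among band pairs at least half a
#' bandwidth apart is taken; the clip value is the segment mean, clamped
#' to \[0, 1\].  Pulsed (glottal) excitation synchronizes envelopes across
#' bands, broadband noise does not.
#'
#' @param clip an `audio_clip`.
#' @param segment_s segment length for the correlation (default 0.5 s).
#' @return scalar in \[0, 1\].
#' @export
gne_ratio <- function(clip, segment_s = 0.5) {
  fs_t <- 10000
  s <- clip$samples
  fs <- clip$sample_rate_hz
  n <- length(s)
  # band-limit below the target Nyquist, then resample by interpolation
  sp <- fft(s)
  fbin <- (seq_len(n) - 1L) * fs / n
  sp[fbin > 4500 & fbin < fs - 4500] <- 0
  s_lp <- Re(fft(sp, inverse = TRUE)) / n
  t_old <- (seq_len(n) - 1L) / fs
  t_new <- seq(0, t_old[n], by = 1 / fs_t)
  s10 <- approx(t_old, s_lp, xout = t_new)$y
  m <- length(s10)

  centers <- seq(1500, 3500, by = 500)
  half_bw <- 1500
  spec <- fft(s10)
  freqs <- (seq_len(m) - 1L) * fs_t / m
  env <- matrix(0, m, length(centers))
  for (k in seq_along(centers)) {
    keep <- freqs >= (centers[k] - half_bw) & freqs <= (centers[k] + half_bw)
    bandsp <- rep(0 + 0i, m)
    bandsp[keep] <- spec[keep] * 2      # analytic signal: positive freqs only
    env[, k] <- Mod(fft(bandsp, inverse = TRUE) / m)
  }
  pairs <- which(outer(centers, centers, function(a, b) (b - a) >= half_bw),
                 arr.ind = TRUE)
  seg_len <- round(segment_s * fs_t)
  n_seg <- max(1L, floor(m / seg_len))
  vals <- vapply(seq_len(n_seg), function(g) {
    idx <- ((g - 1L) * seg_len + 1L):min(g * seg_len, m)
    cors <- apply(pairs, 1L, function(p) {
      suppressWarnings(stats::cor(env[idx, p[1L]], env[idx, p[2L]]))
    })
    cors <- cors[is.finite(cors)]
    if (!length(cors)) 0 else max(cors)
  }, numeric(1))
  max(0, min(1, mean(vals)))
}

#' Harmonic difference, high-frequency noise fraction and PSD band summary
#'
#' * `h1_h2_db`: level difference between the first and second harmonic
#'   magnitudes, measured on a zero-padded Hann-windowed mid-clip segment
#'   with parabolic peak interpolation around f0 and 2 f0.
#' * `hf_noise_6000`: fraction of spectral energy above 6000 Hz (NA when
#'   the sampling rate cannot observe 6 kHz).
#' * `psd_summary`: mean Welch power-spectral-density level in the 0-1 kHz
#'   band minus the 1-5 kHz band, in dB.
#'
#' @param clip an `audio_clip`.
#' @param pitch a `pitch_track` (for f0); `h1_h2_db` is NA when unvoiced.
#' @param segment_s analysis segment for the harmonic measurement.
#' @return named numeric vector `h1_h2_db`, `hf_noise_6000`, `psd_summary`.
#' @export
spectral_noise_measures <- function(clip, pitch, segment_s = 0.5) {
  fs <- clip$sample_rate_hz
  s <- clip$samples
  n <- length(s)

  h1h2 <- NA_real_
  if (!isTRUE(pitch$unvoiced_clip)) {
    f0 <- mean(pitch$f0_hz[pitch$voiced])
    seg_len <- min(n, round(segment_s * fs))
    start <- max(1L, floor((n - seg_len) / 2))
    seg <- s[start:(start + seg_len - 1L)]
    seg <- (seg - mean(seg)) * hann_window(seg_len)
    nfft <- next_pow2(2L * seg_len)
    amp <- Mod(fft(c(seg, rep(0, nfft - seg_len))))[seq_len(nfft / 2)]
    freqs <- (seq_len(nfft / 2) - 1L) * fs / nfft
    peak_level <- function(f_target) {
      band <- which(freqs >= 0.8 * f_target & freqs <= 1.2 * f_target)
      if (length(band) < 3L) return(NA_real_)
      i <- band[which.max(amp[band])]
      pk <- parabolic_peak(amp, i)
      20 * log10(max(pk$height, 1e-12))
    }
    h1h2 <- peak_level(f0) - peak_level(2 * f0)
  }

  x <- s - mean(s)
  pow <- Mod(fft(x))^2
  half <- seq(2L, floor(n / 2) + 1L)
  freqs_all <- (half - 1L) * fs / n
  ptot <- sum(pow[half])
  hf <- if (fs < 12000) NA_real_ else
    sum(pow[half][freqs_all > 6000]) / max(ptot, 1e-24)

  # Welch: averaged periodograms of Hann-windowed 40 ms frames
  grid <- frame_signal(clip, 0.040, 0.020)
  L <- nrow(grid$frames)
  nfft <- next_pow2(L)
  wfr <- grid$frames * grid$window
  spf <- mvfft(rbind(wfr, matrix(0, nfft - L, ncol(wfr))))
  psd <- rowMeans(Mod(spf[seq(2L, nfft / 2 + 1L), , drop = FALSE])^2)
  fpsd <- (seq(2L, nfft / 2 + 1L) - 1L) * fs / nfft
  psd_summary <- 10 * log10(mean(psd[fpsd <= 1000]) + 1e-24) -
    10 * log10(mean(psd[fpsd > 1000 & fpsd <= 5000]) + 1e-24)

  c(h1_h2_db = h1h2, hf_noise_6000 = hf, psd_summary = psd_summary)
}

#' Default Acoustic Breathiness Index coefficients
#'
#' The index is an affine combination of breathiness-related measures.
#' The coefficient set is configuration, not a fixed constant of the
#' package: these defaults are direction-correct package choices (breathier
#' voices score higher — lower CPPS/HNR/GNE, higher shimmer, harmonic
#' difference and high-frequency noise) and can be replaced wholesale,
#' e.g. with a set transcribed from a published regression, via the
#' `coefficients` argument of [abi_score()] or a YAML config.
#'
#' @return named numeric vector with an `intercept` entry plus one slope
#'   per component.
#' @export
abi_default_coefficients <- function() {
  c(intercept = 6.50,
    cpp_smoothed_db = -0.25,
    hnr_db = -0.13,
    gne_ratio = -2.00,
    h1_h2_db = 0.05,
    hf_noise_6000 = 4.00,
    shimmer_db = 0.60,
    psd_summary = -0.02)
}

#' Acoustic Breathiness Index
#'
#' Affine combination of the breathiness components under a configurable
#' coefficient set (see [abi_default_coefficients()]).
#'
#' @param components named numeric vector/list holding every component the
#'   coefficient set names (besides `intercept`).
#' @param coefficients named coefficient vector with an `intercept` entry.
#' @return scalar index; NA (with attribute `missing_components`) when any
#'   required component is absent or NA.
#' @export
abi_score <- function(components, coefficients = abi_default_coefficients()) {
  components <- unlist(components)
  needed <- setdiff(names(coefficients), "intercept")
  missing <- needed[!(needed %in% names(components)) |
                      is.na(components[needed])]
  if (length(missing)) {
    out <- NA_real_
    attr(out, "missing_components") <- missing
    return(out)
  }
  unname(coefficients[["intercept"]] +
           sum(coefficients[needed] * components[needed]))
}

# Mel scale helpers
hz_to_mel <- function(f) 2595 * log10(1 + f / 700)
mel_to_hz <- function(m) 700 * (10^(m / 2595) - 1)

mel_filterbank <- function(n_mels, nfft, fs, f_min = 0, f_max = fs / 2) {
  mels <- seq(hz_to_mel(f_min), hz_to_mel(f_max), length.out = n_mels + 2L)
  hz <- mel_to_hz(mels)
  bins <- (seq_len(nfft / 2 + 1L) - 1L) * fs / nfft
  fb <- matrix(0, n_mels, length(bins))
  for (k in seq_len(n_mels)) {
    lo <- hz[k]; ce <- hz[k + 1L]; hi <- hz[k + 2L]
    up <- (bins - lo) / max(ce - lo, 1e-9)
    down <- (hi - bins) / max(hi - ce, 1e-9)
    fb[k, ] <- pmax(0, pmin(up, down))
  }
  fb
}

#' MFCC summary for one clip
#'
#' 13 Mel-frequency cepstral coefficients from a 26-filter mel bank on
#' the standard frame grid, aggregated as per-coefficient mean and
#' population standard deviation over frames (26 values per clip).
#'
#' @param clip an `audio_clip`.
#' @param n_mfcc,n_mels coefficient and filter counts (defaults 13 / 26).
#' @param frame_length_s,hop_s analysis grid.
#' @return named numeric vector `mfcc1_mean` .. `mfcc13_mean`,
#'   `mfcc1_std` .. `mfcc13_std`.
#' @export
mfcc_summary <- function(clip, n_mfcc = 13L, n_mels = 26L,
                         frame_length_s = 0.040, hop_s = 0.010) {
  grid <- frame_signal(clip, frame_length_s, hop_s)
  fs <- grid$sample_rate_hz
  L <- nrow(grid$frames)
  nfft <- next_pow2(L)
  wfr <- grid$frames * grid$window
  sp <- mvfft(rbind(wfr, matrix(0, nfft - L, ncol(wfr))))
  pow <- Mod(sp[seq_len(nfft / 2 + 1L), , drop = FALSE])^2
  fb <- mel_filterbank(n_mels, nfft, fs)
  melE <- log(fb %*% pow + 1e-12)
  # orthonormal DCT-II over the mel axis
  k <- seq_len(n_mfcc)
  dct <- sqrt(2 / n_mels) *
    cos(outer(k - 1L, seq_len(n_mels) - 0.5) * pi / n_mels)
  dct[1L, ] <- dct[1L, ] / sqrt(2)
  cc <- dct %*% melE
  means <- rowMeans(cc)
  stds <- apply(cc, 1L, pop_sd)
  setNames(c(means, stds),
           c(paste0("mfcc", k, "_mean"), paste0("mfcc", k, "_std")))
}

#' PCA reduction of cohort MFCC summaries
#'
#' PCA is fitted on the training rows only (centering, no rescaling) and
#' all rows are projected onto the top `n_components` components; when the
#' training matrix has lower rank the missing components are zero-padded
#' with a warning.
#'
#' @param mfcc_matrix participants x 26 matrix of [mfcc_summary()] rows.
#' @param train_mask logical vector marking training rows.
#' @param n_components number of retained components (default 10).
#' @return list: `scores` (participants x n_components, columns
#'   `mfcc_pc1` ..), `rotation`, `center`, `n_effective`.
#' @export
mfcc_pca <- function(mfcc_matrix, train_mask, n_components = 10L) {
  stopifnot(nrow(mfcc_matrix) == length(train_mask))
  tr <- mfcc_matrix[train_mask, , drop = FALSE]
  pc <- prcomp(tr, center = TRUE, scale. = FALSE)
  sdev_ok <- pc$sdev > 1e-10
  k_eff <- min(n_components, sum(sdev_ok), ncol(pc$rotation))
  scores <- sweep(mfcc_matrix, 2L, pc$center) %*%
    pc$rotation[, seq_len(k_eff), drop = FALSE]
  if (k_eff < n_components) {
    warning(sprintf("training rank %d < %d components; zero-padding",
                    k_eff, n_components))
    scores <- cbind(scores, matrix(0, nrow(scores), n_components - k_eff))
  }
  colnames(scores) <- paste0("mfcc_pc", seq_len(n_components))
  rotation <- pc$rotation[, seq_len(k_eff), drop = FALSE]
  if (k_eff < n_components) {
    # keep rotation conformable with the zero-padded score columns
    rotation <- cbind(rotation,
                      matrix(0, nrow(rotation), n_components - k_eff))
  }
  colnames(rotation) <- colnames(scores)
  list(scores = scores, rotation = rotation,
       center = pc$center, n_effective = k_eff)
}

#' All single-clip voice features
#'
#' Computes the pitch/volume statistics, frame descriptors, breathiness
#' components and the Acoustic Breathiness Index for one clip; the MFCC
#' summary is returned separately because its PCA reduction is fitted at
#' cohort level (training rows only).
#'
#' @param clip an `audio_clip`.
#' @param abi_coefficients coefficient set for [abi_score()].
#' @return list: `features` — named numeric vector with a `voice_` prefix
#'   (20 values, NA where unvoiced measures are undefined); `mfcc` — the
#'   26-value [mfcc_summary()] vector; `pitch` — the `pitch_track`.
#' @export
voice_feature_block <- function(clip,
                                abi_coefficients = abi_default_coefficients()) {
  grid <- frame_signal(clip)
  pitch <- pitch_track(grid)
  desc <- frame_descriptors(grid)
  shim <- shimmer_db(clip, pitch)
  hnr <- hnr_db(grid, pitch)
  cpp <- cpp_smoothed_db(clip)
  gne <- gne_ratio(clip)
  noise <- spectral_noise_measures(clip, pitch)
  comps <- c(cpp_smoothed_db = cpp, hnr_db = hnr, gne_ratio = gne,
             shimmer_db = shim, noise)
  abi <- abi_score(comps, abi_coefficients)
  feats <- c(
    pitch_mean_hz = pitch$pitch_mean_hz, pitch_std_hz = pitch$pitch_std_hz,
    desc,
    shimmer_db = unname(shim), hnr_db = unname(hnr),
    cpp_smoothed_db = unname(cpp), gne_ratio = unname(gne),
    h1_h2_db = unname(noise[["h1_h2_db"]]),
    hf_noise_6000 = unname(noise[["hf_noise_6000"]]),
    psd_summary = unname(noise[["psd_summary"]]),
    abi_score = as.numeric(abi)
  )
  names(feats) <- paste0("voice_", names(feats))
  list(features = feats, mfcc = mfcc_summary(clip), pitch = pitch)
}
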