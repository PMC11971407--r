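# Seeded, class-conditional synthetic participants: demographics with the
# published age/smoking marginals, gait and tapping accelerometer traces,
# tap-event streams, and sustained-phonation audio.  Effect magnitudes are
# explicit design parameters of the generator; every draw is a pure
# function of (parameters, seed) and ground-truth generative parameters
# are stored for recovery tests.

#' Default class effect profiles
#'
#' Encodes the directions the disease is known to move each modality:
#' a 4-6 Hz rest/postural tremor component in the accelerometer traces,
#' slower and more variable alternating tapping with more same-button
#' repeats (bradykinesia / impaired alternation), and breathier phonation
#' (more cycle-to-cycle jitter and shimmer, lower harmonics-to-noise
#' ratio).  Magnitudes are generator design choices, validated at load to
#' be strictly "worse" for the PD profile in every configured dimension.
#'
#' @param null_effect if TRUE, the PD profile is made identical to the
#'   control profile (label-only cohort, for chance-level calibration).
#' @return list with elements `control` and `pd`.
#' @export
class_effect_profiles <- function(null_effect = FALSE) {
  control <- list(
    tremor_frequency_hz = NULL, tremor_amplitude = 0,
    tap_interval_mean_s = 0.18, tap_interval_cv = 0.10,
    repeat_tap_probability = 0.02,
    jitter_pct = 0.3, shimmer_db = 0.2, hnr_target_db = 25,
    f0_range_male_hz = c(100, 140), f0_range_female_hz = c(180, 230)
  )
  pd <- list(
    tremor_frequency_hz = c(4, 6), tremor_amplitude = 0.5,
    tap_interval_mean_s = 0.35, tap_interval_cv = 0.35,
    repeat_tap_probability = 0.12,
    jitter_pct = 1.5, shimmer_db = 0.8, hnr_target_db = 12,
    f0_range_male_hz = c(100, 140), f0_range_female_hz = c(180, 230)
  )
  if (null_effect) pd <- control
  profiles <- list(control = control, pd = pd)
  validate_profiles(profiles, allow_equal = null_effect)
  profiles
}

validate_profiles <- function(profiles, allow_equal = FALSE) {
  ctl <- profiles$control; pd <- profiles$pd
  cmp <- if (allow_equal) `>=` else `>`
  checks <- c(
    tremor = cmp(pd$tremor_amplitude, ctl$tremor_amplitude),
    tap_mean = cmp(pd$tap_interval_mean_s, ctl$tap_interval_mean_s),
    tap_cv = cmp(pd$tap_interval_cv, ctl$tap_interval_cv),
    repeats = cmp(pd$repeat_tap_probability, ctl$repeat_tap_probability),
    jitter = cmp(pd$jitter_pct, ctl$jitter_pct),
    shimmer = cmp(pd$shimmer_db, ctl$shimmer_db),
    hnr = cmp(ctl$hnr_target_db, pd$hnr_target_db)
  )
  probs_ok <- all(vapply(profiles, function(p)
    p$repeat_tap_probability >= 0 && p$repeat_tap_probability <= 1 &&
      p$tap_interval_mean_s > 0 && p$tap_interval_cv >= 0 &&
      p$tremor_amplitude >= 0 && p$jitter_pct >= 0 && p$shimmer_db >= 0,
    logical(1)))
  if (!all(checks) || !probs_ok) {
    stop("invalid effect profiles: PD must be at least as impaired as control in every dimension",
         call. = FALSE)
  }
  invisible(profiles)
}

#' Synthesize cohort demographics
#'
#' Labels are balanced exactly (n/2 PD, +/- 1 when n is odd).  Age bands
#' are drawn from class-conditional distributions whose 50/50 mixture
#' reproduces the target marginals (<40 / 40-60 / >60 = 34 / 60 / 100 out
#' of 194) while making PD prevalence increase with age; the smoking
#' marginal (59/194) is reproduced the same way.
#'
#' @param n cohort size.
#' @param seed integer seed.
#' @param marginals list with `age_bands` (3 probabilities) and `smoker`
#'   (probability); defaults to the published totals.
#' @return list of `participant_record`s (no trials attached yet).
#' @export
synth_demographics <- function(n, seed = 1L,
                               marginals = list(
                                 age_bands = c(34, 60, 100) / 194,
                                 smoker = 59 / 194)) {
  if (n == 0L) return(list())
  m <- marginals$age_bands
  if (abs(sum(m) - 1) > 1e-6 || any(m < 0)) {
    stop("age-band marginals must be a probability vector", call. = FALSE)
  }
  # class-conditional band probabilities: mixture = marginal, PD older
  pd_bands <- c(0.09, 0.26, 0.65)
  # rescale the PD skew if the requested marginal makes any control prob negative
  ctl_bands <- 2 * m - pd_bands
  if (any(ctl_bands < 0)) {
    pd_bands <- m; ctl_bands <- m
  }
  smoker_pd <- min(0.95, 2 * marginals$smoker - 0.25)
  smoker_ctl <- 2 * marginals$smoker - smoker_pd

  set.seed(child_seed(seed, "demographics"))
  n_pd <- floor(n / 2)
  labels <- sample(c(rep("PD", n_pd), rep("control", n - n_pd)))
  band_edges <- list(c(18, 39), c(40, 60), c(61, 85))
  lapply(seq_len(n), function(i) {
    is_pd <- labels[i] == "PD"
    band <- sample.int(3L, 1L, prob = if (is_pd) pd_bands else ctl_bands)
    age <- round(runif(1, band_edges[[band]][1L], band_edges[[band]][2L]))
    participant_record(
      participant_id = sprintf("S%04d", i),
      age = age,
      gender = sample(c("male", "female"), 1L),
      smoker = runif(1) < (if (is_pd) smoker_pd else smoker_ctl),
      label = labels[i]
    )
  })
}

#' Synthesize a gait accelerometer trace
#'
#' The vertical axis carries a 1 g gravity baseline plus a walking
#' oscillation (~2 Hz) with a second harmonic, Gaussian sensor noise, and
#' — for a PD profile — a tremor sinusoid at the profile frequency; the
#' horizontal axes are scaled, phase-shifted correlates.
#'
#' @param profile one element of [class_effect_profiles()].
#' @param duration_s,fs trace length and sampling rate (defaults 30 s,
#'   100 Hz).
#' @param seed integer seed.
#' @param walk_amplitude,harmonic_amplitude,noise_sd signal-family
#'   parameters (defaults 0.5 / 0.15 / 0.1 g).
#' @param walk_frequency_hz optional fixed walking frequency (default:
#'   drawn uniformly from 1.8-2.2 Hz).
#' @return an `accel_trace` with attribute `ground_truth` (the drawn
#'   walking and tremor parameters).
#' @export
synth_gait <- function(profile, duration_s = 30, fs = 100, seed = 1L,
                       walk_amplitude = 0.5, harmonic_amplitude = 0.15,
                       noise_sd = 0.1, walk_frequency_hz = NULL) {
  set.seed(child_seed(seed, "gait"))
  t <- seq(0, duration_s - 1 / fs, by = 1 / fs)
  f_walk <- walk_frequency_hz %||% runif(1, 1.8, 2.2)
  f_trem <- if (!is.null(profile$tremor_frequency_hz)) {
    runif(1, profile$tremor_frequency_hz[1L], profile$tremor_frequency_hz[2L])
  } else {
    NA_real_
  }
  a_trem <- profile$tremor_amplitude * walk_amplitude
  phase <- runif(3, 0, 2 * pi)
  tremor <- function(scale, ph) {
    if (is.na(f_trem) || a_trem == 0) 0 else
      scale * a_trem * sin(2 * pi * f_trem * t + ph)
  }
  z <- 1 + walk_amplitude * sin(2 * pi * f_walk * t) +
    harmonic_amplitude * sin(2 * pi * 2 * f_walk * t + phase[1L]) +
    tremor(1, 0) + rnorm(length(t), 0, noise_sd)
  x <- 0.5 * walk_amplitude * sin(2 * pi * f_walk * t + phase[2L]) +
    tremor(0.6, phase[2L]) + rnorm(length(t), 0, noise_sd)
  y <- 0.4 * walk_amplitude * sin(2 * pi * f_walk * t + phase[3L]) +
    tremor(0.5, phase[3L]) + rnorm(length(t), 0, noise_sd)
  out <- accel_trace(t, x, y, z, unit = "g", source_activity = "gait")
  attr(out, "ground_truth") <- list(
    walk_frequency_hz = f_walk, tremor_frequency_hz = f_trem,
    tremor_amplitude = a_trem, walk_amplitude = walk_amplitude,
    noise_sd = noise_sd)
  out
}

#' Synthesize a tapping test
#'
#' Alternating-button events with lognormal inter-tap intervals (mean and
#' coefficient of variation from the profile; lognormal for positivity
#' and right skew), independent same-button repeats with the profile
#' probability, and an accelerometer trace carrying a decaying transient
#' per tap plus sensor noise and any profile tremor.
#'
#' @param profile one element of [class_effect_profiles()].
#' @param window_seconds test window (default 20 s).
#' @param fs accelerometer rate (default 100 Hz).
#' @param seed integer seed.
#' @return list: `events` (a `tap_events`), `trace` (an `accel_trace`),
#'   each with `ground_truth` attributes.
#' @export
synth_taps <- function(profile, window_seconds = 20, fs = 100, seed = 1L) {
  set.seed(child_seed(seed, "taps"))
  m <- profile$tap_interval_mean_s
  cv <- max(profile$tap_interval_cv, 1e-6)
  sig2 <- log(1 + cv^2)
  mu <- log(m) - sig2 / 2
  n_max <- ceiling(window_seconds / m * 2) + 20L
  gaps <- rlnorm(n_max, mu, sqrt(sig2))
  times <- cumsum(gaps)
  times <- times[times <= window_seconds]
  n <- length(times)
  buttons <- character(n)
  if (n > 0L) {
    buttons[1L] <- sample(c("left", "right"), 1L)
    if (n > 1L) {
      rep_draw <- runif(n - 1L) < profile$repeat_tap_probability
      for (i in 2:n) {
        buttons[i] <- if (rep_draw[i - 1L]) buttons[i - 1L] else
          setdiff(c("left", "right"), buttons[i - 1L])
      }
    }
  }
  ev <- tap_events(times, buttons, window_seconds)
  attr(ev, "ground_truth") <- list(
    interval_mean_s = m, interval_cv = cv,
    repeat_probability = profile$repeat_tap_probability)

  t <- seq(0, window_seconds - 1 / fs, by = 1 / fs)
  z <- 1 + rnorm(length(t), 0, 0.05)
  for (tt in times) {
    idx <- which(t >= tt & t < tt + 0.08)
    if (length(idx)) z[idx] <- z[idx] + 0.5 * exp(-(t[idx] - tt) / 0.02)
  }
  a_trem <- profile$tremor_amplitude * 0.15
  f_trem <- if (!is.null(profile$tremor_frequency_hz)) {
    runif(1, profile$tremor_frequency_hz[1L], profile$tremor_frequency_hz[2L])
  } else {
    NA_real_
  }
  if (!is.na(f_trem) && a_trem > 0) {
    z <- z + a_trem * sin(2 * pi * f_trem * t)
  }
  x <- rnorm(length(t), 0, 0.05) +
    (if (!is.na(f_trem) && a_trem > 0) 0.6 * a_trem * sin(2 * pi * f_trem * t + 1) else 0)
  y <- rnorm(length(t), 0, 0.05)
  tr <- accel_trace(t, x, y, z, unit = "g", source_activity = "tapping")
  attr(tr, "ground_truth") <- list(tremor_frequency_hz = f_trem,
                                   tremor_amplitude = a_trem)
  list(events = ev, trace = tr)
}

#' Synthesize a sustained-vowel clip
#'
#' Harmonic source (1/k amplitude rolloff, harmonics filling the band up
#' to 90% of Nyquist like a glottal pulse train) with per-cycle
#' period jitter (percent of the period) and amplitude shimmer
#' (per-cycle log-amplitude scaled so the expected absolute consecutive
#' dB difference equals the profile's shimmer), plus white noise scaled
#' to hit the target harmonics-to-noise ratio.  Cycle phase accumulates
#' exactly one turn per cycle so frequency modulation is continuous.
#'
#' @param profile one element of [class_effect_profiles()].
#' @param duration_s,fs clip length and rate (defaults 10 s, 16 kHz).
#' @param seed integer seed.
#' @param gender `"male"` or `"female"` — selects the f0 range.
#' @param f0_hz optional fixed fundamental (overrides the range draw).
#' @param n_harmonics number of harmonics; the default fills the band up
#'   to 0.9 x Nyquist (capped at 60).
#' @return an `audio_clip` with attribute `ground_truth`.
#' @export
synth_voice <- function(profile, duration_s = 10, fs = 16000, seed = 1L,
                        gender = "male", f0_hz = NULL, n_harmonics = NULL) {
  set.seed(child_seed(seed, "voice"))
  if (is.null(f0_hz)) {
    rng <- if (identical(gender, "female")) profile$f0_range_female_hz
           else profile$f0_range_male_hz
    f0_hz <- runif(1, rng[1L], rng[2L])
  }
  if (is.null(n_harmonics)) {
    n_harmonics <- max(3L, min(60L, floor(0.45 * fs / f0_hz)))
  }
  T0 <- 1 / f0_hz
  n_cycles <- ceiling(duration_s / T0 * 1.3) + 5L
  jit <- profile$jitter_pct / 100
  periods <- T0 * (1 + jit * rnorm(n_cycles))
  periods <- pmax(periods, 0.2 * T0)
  # per-cycle dB scatter s such that E|diff of consecutive dB| = shimmer_db
  s_db <- profile$shimmer_db * sqrt(pi) / 2
  amps <- 10^((s_db * rnorm(n_cycles)) / 20)
  starts <- c(0, cumsum(periods))
  t <- seq(0, duration_s - 1 / fs, by = 1 / fs)
  ci <- findInterval(t, starts)
  ci[ci < 1L] <- 1L; ci[ci > n_cycles] <- n_cycles
  phase <- 2 * pi * ((ci - 1L) + (t - starts[ci]) / periods[ci])
  s <- numeric(length(t))
  for (k in seq_len(n_harmonics)) s <- s + sin(k * phase) / k
  s <- s * amps[ci]
  p_harm <- mean(s^2)
  sigma <- sqrt(p_harm / 10^(profile$hnr_target_db / 10))
  s <- s + rnorm(length(t), 0, sigma)
  s <- 0.9 * s / max(abs(s))
  clip <- audio_clip(s, fs)
  attr(clip, "ground_truth") <- list(
    f0_hz = f0_hz, jitter_pct = profile$jitter_pct,
    shimmer_db = profile$shimmer_db, hnr_target_db = profile$hnr_target_db)
  clip
}

#' Generate a complete synthetic cohort
#'
#' Balanced labels, all four modalities per participant, deterministic
#' under a fixed seed.  Trials are attached in memory; with `out_dir` the
#' same CSV/JSON/WAV layouts the readers accept are written to disk along
#' with a cohort manifest and a ground-truth parameter file.
#'
#' @param n cohort size (default 194; >= 4).
#' @param profiles effect profiles (default [class_effect_profiles()]).
#' @param seed integer seed.
#' @param train_n,test_n split sizes passed to [assemble_cohort()]
#'   (defaults 164/30 scaled to `n`).
#' @param gait_duration_s,voice_duration_s per-modality durations.
#' @param out_dir optional directory for on-disk output.
#' @return a `cohort_table` whose records carry in-memory trials and a
#'   `ground_truth` attribute per participant.
#' @export
synth_cohort <- function(n = 194L, profiles = class_effect_profiles(),
                         seed = 1L, train_n = NULL, test_n = NULL,
                         gait_duration_s = 30, voice_duration_s = 10,
                         out_dir = NULL) {
  if (n < 4L) stop("need n >= 4", call. = FALSE)
  validate_profiles(profiles, allow_equal = TRUE)
  recs <- synth_demographics(n, seed = seed)
  if (is.null(train_n)) {
    train_n <- round(n * 164 / 194)
    test_n <- n - train_n
  }
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  gt <- list()
  for (i in seq_along(recs)) {
    r <- recs[[i]]
    prof <- if (r$label == "PD") profiles$pd else profiles$control
    pseed <- child_seed(seed, paste0("participant-", r$participant_id))
    gait <- synth_gait(prof, duration_s = gait_duration_s, seed = pseed)
    taps <- synth_taps(prof, seed = pseed)
    clip <- synth_voice(prof, duration_s = voice_duration_s, seed = pseed,
                        gender = r$gender)
    gt[[r$participant_id]] <- list(
      label = r$label,
      gait = attr(gait, "ground_truth"),
      taps = attr(taps$events, "ground_truth"),
      voice = attr(clip, "ground_truth"))
    if (is.null(out_dir)) {
      recs[[i]]$trial_refs <- list(
        gait = list(gait),
        tapping = list(events = taps$events, trace = taps$trace),
        voice = list(clip))
    } else {
      pdir <- file.path(out_dir, r$participant_id)
      dir.create(pdir, showWarnings = FALSE)
      gait_p <- file.path(pdir, "gait.csv")
      ev_p <- file.path(pdir, "taps.csv")
      tap_tr_p <- file.path(pdir, "tap_accel.csv")
      wav_p <- file.path(pdir, "voice.wav")
      write_accel_trace(gait, gait_p)
      write_tap_events(taps$events, ev_p)
      write_accel_trace(taps$trace, tap_tr_p)
      write_audio(clip, wav_p)
      recs[[i]]$trial_refs <- list(
        gait = gait_p,
        tapping = list(events = ev_p, trace = tap_tr_p),
        voice = wav_p)
    }
  }
  cohort <- assemble_cohort(recs, train_n = train_n, test_n = test_n,
                            seed = seed)
  attr(cohort, "ground_truth") <- gt
  if (!is.null(out_dir)) {
    write.csv(cbind(cohort$split,
                    age = vapply(cohort$records, `[[`, numeric(1), "age"),
                    gender = vapply(cohort$records, `[[`, character(1), "gender"),
                    smoker = vapply(cohort$records, `[[`, logical(1), "smoker")),
              file.path(out_dir, "manifest.csv"), row.names = FALSE)
    jsonlite::write_json(gt, file.path(out_dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  cohort
}
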