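# Shared fixture builders for the test suite.  Everything is generated
# programmatically; no binary fixtures are checked in.

# A clip holding an arbitrary waveform without tripping the sustained-vowel
# duration flag logic in tests that don't care about it.
make_clip <- function(samples, fs) {
  audio_clip(samples, fs, duration_bounds_s = c(0, Inf))
}

# Pure tone / harmonic-stack clips
tone_clip <- function(f0, duration_s = 1, fs = 16000, amplitude = 0.8,
                      harmonics = 1) {
  t <- seq(0, duration_s - 1 / fs, by = 1 / fs)
  s <- 0
  for (k in seq_len(harmonics)) s <- s + sin(2 * pi * k * f0 * t) / k
  make_clip(amplitude * s / max(abs(s)), fs)
}

noise_clip <- function(duration_s = 1, fs = 16000, sd = 0.2, seed = 1) {
  set.seed(seed)
  make_clip(pmax(pmin(rnorm(round(duration_s * fs), 0, sd), 0.99), -0.99), fs)
}

# Constant-axis accelerometer trace
const_trace <- function(x, y, z, n = 100, fs = 100, activity = "gait") {
  t <- seq(0, by = 1 / fs, length.out = n)
  accel_trace(t, rep(x, n), rep(y, n), rep(z, n), source_activity = activity)
}

# Minimal participant record with in-memory synthetic trials
make_participant <- function(id, label, seed = 1, profile = NULL) {
  prof <- profile %||% (if (label == "PD") class_effect_profiles()$pd
                        else class_effect_profiles()$control)
  taps <- synth_taps(prof, seed = seed)
  participant_record(
    participant_id = id, age = 60, gender = "male", smoker = FALSE,
    label = label,
    trial_refs = list(
      gait = list(synth_gait(prof, duration_s = 10, seed = seed)),
      tapping = list(events = taps$events, trace = taps$trace),
      voice = list(synth_voice(prof, duration_s = 2, seed = seed))))
}

# A tiny kernel spec over d features with uniform weights, unit scalers
toy_kernel_spec <- function(d) {
  structure(list(
    selected_feature_names = paste0("f", seq_len(d)),
    column_scalers = rep(1, d),
    softmax_weights = rep(1 / d, d),
    scale = 1,
    standardization_params = NULL
  ), class = "kernel_spec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
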