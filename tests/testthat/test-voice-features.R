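test_that("frame grid counts match the closed form", {
  g <- frame_signal(tone_clip(100, duration_s = 1, fs = 16000))
  expect_equal(g$n_frames, 97)
  # exactly one frame at the boundary
  g1 <- frame_signal(make_clip(rep(0.1, 640), 16000))
  expect_equal(g1$n_frames, 1)
  expect_error(frame_signal(make_clip(rep(0.1, 320), 16000)), "short")
})

test_that("pitch tracking recovers a 150 Hz harmonic tone", {
  p <- pitch_track(frame_signal(tone_clip(150, harmonics = 4)))
  expect_lt(abs(p$pitch_mean_hz - 150), 2)
  expect_lt(p$pitch_std_hz, 2)
  expect_false(p$unvoiced_clip)
})

test_that("white noise is flagged unvoiced and jitter raises pitch spread", {
  pn <- pitch_track(frame_signal(noise_clip()))
  expect_true(pn$unvoiced_clip)

  prof <- class_effect_profiles()$control
  clean <- prof; clean$jitter_pct <- 0
  jit <- prof; jit$jitter_pct <- 2
  p_clean <- voice_feature_block(
    synth_voice(clean, duration_s = 2, seed = 8, f0_hz = 150))$features
  p_jit <- voice_feature_block(
    synth_voice(jit, duration_s = 2, seed = 8, f0_hz = 150))$features
  expect_lt(abs(p_jit[["voice_pitch_mean_hz"]] - 150), 3)
  expect_gt(p_jit[["voice_pitch_std_hz"]], p_clean[["voice_pitch_std_hz"]])
})

test_that("frame descriptors match single-line spectrum facts", {
  clip <- tone_clip(1000, fs = 16000)
  d <- frame_descriptors(frame_signal(clip))
  expect_equal(unname(d[["zcr_mean"]]), 0.125, tolerance = 0.01)
  expect_lt(abs(d[["spectral_centroid_mean_hz"]] - 1000), 20)
  # rolloff within one bin of the tone
  expect_lt(abs(d[["spectral_rolloff_mean_hz"]] - 1000), 16000 / 1024 + 1)

  silent <- frame_descriptors(frame_signal(make_clip(rep(0, 16000), 16000)))
  expect_true(all(silent == 0))

  # amplitude doubling: volume doubles, shape measures unchanged
  half <- tone_clip(500, amplitude = 0.4)
  full <- tone_clip(500, amplitude = 0.8)
  dh <- frame_descriptors(frame_signal(half))
  df <- frame_descriptors(frame_signal(full))
  expect_equal(unname(df[["volume_mean"]]), 2 * unname(dh[["volume_mean"]]),
               tolerance = 1e-9)
  for (nm in c("zcr_mean", "spectral_centroid_mean_hz",
               "spectral_bandwidth_mean_hz", "spectral_rolloff_mean_hz")) {
    expect_equal(unname(df[[nm]]), unname(dh[[nm]]), tolerance = 1e-9)
  }
})

test_that("shimmer reproduces the closed-form examples", {
  fs <- 16000; f0 <- 100
  t <- seq(0, 1 - 1 / fs, by = 1 / fs)
  # perfectly periodic tone -> ~0 dB
  tone <- make_clip(0.9 * sin(2 * pi * f0 * t), fs)
  p <- pitch_track(frame_signal(tone))
  expect_lt(abs(shimmer_db(tone, p)), 0.1)

  # alternating cycle amplitudes A, 2A with the known 100 Hz track
  alt <- make_clip((1 + floor(t * f0) %% 2) * sin(2 * pi * f0 * t) / 2.2, fs)
  track <- structure(list(f0_hz = rep(f0, 5), voiced = rep(TRUE, 5),
                          unvoiced_clip = FALSE), class = "pitch_track")
  expect_equal(shimmer_db(alt, track), 20 * log10(2), tolerance = 0.1)
})

test_that("injected 1 dB shimmer is recovered within 0.3 dB", {
  prof <- class_effect_profiles()$control
  prof$shimmer_db <- 1; prof$hnr_target_db <- 60; prof$jitter_pct <- 0.1
  est <- vapply(1:5, function(s)
    voice_feature_block(synth_voice(prof, seed = s,
                                    gender = "male"))$features[["voice_shimmer_db"]],
    numeric(1))
  expect_true(all(abs(est - 1) <= 0.3))
})

test_that("unvoiced clip gives missing shimmer and HNR", {
  nz <- noise_clip()
  p <- pitch_track(frame_signal(nz))
  expect_true(is.na(shimmer_db(nz, p)))
  expect_true(is.na(hnr_db(frame_signal(nz), p)))
})

test_that("HNR hits the clean and equal-power-noise anchors", {
  clean <- tone_clip(150, harmonics = 3)
  g <- frame_signal(clean)
  expect_gte(hnr_db(g, pitch_track(g)), 30)

  set.seed(5)
  fs <- 16000
  t <- seq(0, 1 - 1 / fs, by = 1 / fs)
  s <- sin(2 * pi * 150 * t)
  noisy <- s + rnorm(length(s), 0, sqrt(mean(s^2)))
  clip <- make_clip(0.5 * noisy / max(abs(noisy)), fs)
  g2 <- frame_signal(clip)
  h <- hnr_db(g2, pitch_track(g2))
  expect_lt(abs(h), 1.5)
})

test_that("CPPs separates periodic from noise and is gain-invariant", {
  tone <- tone_clip(150, harmonics = 6)
  nz <- noise_clip()
  cp_tone <- cpp_smoothed_db(tone)
  cp_noise <- cpp_smoothed_db(nz)
  expect_gte(cp_tone - cp_noise, 5)

  quiet <- make_clip(tone$samples / 10, tone$sample_rate_hz)
  expect_equal(cpp_smoothed_db(quiet), cp_tone, tolerance = 0.1)
})

test_that("GNE is high for pulsed excitation, lower for noise, deterministic", {
  pulsed <- synth_voice(class_effect_profiles()$control, duration_s = 2,
                        seed = 2, f0_hz = 120)
  g1 <- gne_ratio(pulsed)
  expect_gt(g1, 0.8)
  expect_identical(gne_ratio(pulsed), g1)
  expect_lt(gne_ratio(noise_clip(duration_s = 2)), g1)
})

test_that("spectral noise measures match their closed forms", {
  fs <- 16000
  t <- seq(0, 1 - 1 / fs, by = 1 / fs)
  s <- sin(2 * pi * 150 * t) + 0.5 * sin(2 * pi * 300 * t)
  clip <- make_clip(0.5 * s / max(abs(s)), fs)
  g <- frame_signal(clip)
  m <- spectral_noise_measures(clip, pitch_track(g))
  expect_equal(unname(m[["h1_h2_db"]]), 20 * log10(2), tolerance = 0.3)

  tone1k <- tone_clip(1000, fs = 16000)
  m2 <- spectral_noise_measures(tone1k, pitch_track(frame_signal(tone1k)))
  expect_lt(m2[["hf_noise_6000"]], 0.01)

  m3 <- spectral_noise_measures(noise_clip(), structure(
    list(unvoiced_clip = TRUE), class = "pitch_track"))
  expect_equal(unname(m3[["hf_noise_6000"]]), 0.25, tolerance = 0.03)
  expect_true(is.na(m3[["h1_h2_db"]]))

  lowfs <- tone_clip(200, fs = 8000)
  m4 <- spectral_noise_measures(lowfs, pitch_track(frame_signal(lowfs)))
  expect_true(is.na(m4[["hf_noise_6000"]]))
})

test_that("ABI is an affine combination with missing-component handling", {
  comps <- c(cpp_smoothed_db = 10, hnr_db = 20, gne_ratio = 0.9,
             shimmer_db = 0.3, h1_h2_db = 5, hf_noise_6000 = 0.01,
             psd_summary = 30)
  co <- abi_default_coefficients()
  co[] <- 0; co[["intercept"]] <- 1
  expect_equal(as.numeric(abi_score(comps, co)), 1)

  co2 <- abi_default_coefficients()
  manual <- co2[["intercept"]] +
    sum(co2[setdiff(names(co2), "intercept")] *
          comps[setdiff(names(co2), "intercept")])
  expect_equal(as.numeric(abi_score(comps, co2)), unname(manual))

  comps_missing <- comps
  comps_missing[["hnr_db"]] <- NA_real_
  a <- abi_score(comps_missing, co2)
  expect_true(is.na(a))
  expect_true("hnr_db" %in% attr(a, "missing_components"))
})

test_that("MFCC summary is 26 values and PCA honors train-only centering", {
  clip <- synth_voice(class_effect_profiles()$control, duration_s = 1,
                      seed = 3, f0_hz = 130)
  mf <- mfcc_summary(clip)
  expect_length(mf, 26)

  set.seed(10)
  M <- matrix(rnorm(20 * 26), 20, 26)
  mask <- rep(c(TRUE, FALSE), c(14, 6))
  pca <- mfcc_pca(M, mask, 10)
  expect_equal(dim(pca$scores), c(20, 10))
  # projection of the training mean -> zero vector
  mu <- colMeans(M[mask, ])
  proj <- drop((mu - pca$center) %*% pca$rotation)
  expect_true(all(abs(proj) < 1e-10))

  # rank-2 training matrix -> warning and zero-padding
  low <- matrix(rnorm(12 * 2), 12, 2) %*% matrix(rnorm(2 * 26), 2, 26)
  expect_warning(pl <- mfcc_pca(low, rep(TRUE, 12), 10), "rank|zero-padding")
  expect_true(all(pl$scores[, (pl$n_effective + 1):10] == 0))

  # reconstruction from all components recovers the original
  # (20 train rows have centered rank 19, so this also warns)
  expect_warning(pca_full <- mfcc_pca(M, rep(TRUE, 20), 20), "rank")
  rec <- sweep(pca_full$scores %*% t(pca_full$rotation), 2L,
               -pca_full$center)
  expect_equal(rec, M, tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("voice feature block emits the documented 20 features plus MFCCs", {
  clip <- synth_voice(class_effect_profiles()$control, duration_s = 2,
                      seed = 6, f0_hz = 110)
  vb <- voice_feature_block(clip)
  expect_length(vb$features, 20)
  expect_true(all(startsWith(names(vb$features), "voice_")))
  expect_length(vb$mfcc, 26)
  expect_true(vb$features[["voice_gne_ratio"]] >= 0 &&
                vb$features[["voice_gne_ratio"]] <= 1)
})
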