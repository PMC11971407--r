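test_that("accel CSV reads a regular grid unchanged", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("t,x,y,z", "0,0,0,0", "0.01,0,0,0", "0.02,0,0,0", "0.03,0,0,0"), p)
  tr <- read_accel_trace(p)
  expect_equal(tr$sample_rate_hz, 100)
  expect_length(tr$x, 4)
  expect_true(all(tr$x == 0) && all(tr$y == 0) && all(tr$z == 0))
})

test_that("irregular timestamps resample to the median rate with linear interpolation", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("t,x,y,z", "0,0,0,1", "0.01,1,0,3", "0.03,3,0,7"), p)
  tr <- read_accel_trace(p)
  expect_equal(tr$sample_rate_hz, 100)
  expect_length(tr$x, 4)
  # value at t=0.02 is the midpoint of neighbours (1 and 3)
  expect_equal(tr$x[3], 2)
  expect_equal(tr$z[3], 5)
})

test_that("malformed accel row raises a parse error naming the line", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("t,x,y,z", "0,0,0,0", "0.01,NaN,0,0"), p)
  expect_error(read_accel_trace(p), "line 2|row 2", ignore.case = TRUE)
})

test_that("fewer than 2 samples is an error", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("t,x,y,z", "0,0,0,0"), p)
  expect_error(read_accel_trace(p))
})

test_that("json_records dialect parses and matches CSV", {
  pj <- withr::local_tempfile(fileext = ".json")
  writeLines('[{"timestamp":0,"x":1,"y":2,"z":3},{"timestamp":0.01,"x":4,"y":5,"z":6}]', pj)
  tr <- read_accel_trace(pj, dialect = "json_records")
  expect_equal(tr$x, c(1, 4))
  expect_equal(tr$z, c(3, 6))
})

test_that("accel write/read round-trips to 1e-9", {
  tr <- synth_gait(class_effect_profiles()$control, duration_s = 2, seed = 3)
  p <- withr::local_tempfile(fileext = ".csv")
  write_accel_trace(tr, p)
  tr2 <- read_accel_trace(p)
  expect_equal(tr2$x, tr$x, tolerance = 1e-9)
  expect_equal(tr2$z, tr$z, tolerance = 1e-9)
})

test_that("tap events are kept, dropped past the window, and sorted", {
  tp <- tap_events(c(0.1, 0.3), c("L", "R"), 20)
  expect_length(tp$times, 2)
  expect_equal(tp$n_dropped, 0)

  tp2 <- tap_events(c(0.1, 21.0), c("left", "right"), 20)
  expect_length(tp2$times, 1)
  expect_equal(tp2$n_dropped, 1)

  tp3 <- tap_events(c(0.3, 0.1), c("R", "L"), 20)
  expect_equal(tp3$times, c(0.1, 0.3))
  expect_equal(tp3$buttons, c("left", "right"))
})

test_that("unknown button labels are rejected; empty series is flagged", {
  expect_error(tap_events(0.5, "middle"), "button")
  e <- tap_events(numeric(0), character(0))
  expect_true(e$empty)
})

test_that("tap events round-trip exactly through CSV", {
  tp <- tap_events(c(0.12, 0.5, 1.75), c("left", "right", "left"))
  p <- withr::local_tempfile(fileext = ".csv")
  write_tap_events(tp, p)
  tp2 <- read_tap_events(p)
  expect_identical(tp2$times, tp$times)
  expect_identical(tp2$buttons, tp$buttons)
})

test_that("16-bit WAV scaling, stereo downmix, and duration flag", {
  fs <- 8000
  p <- withr::local_tempfile(fileext = ".wav")
  # full-scale constant: write int 32767 by using samples = 32767/32768
  clip <- audio_clip(rep(32767 / 32768, fs), fs, duration_bounds_s = c(0, 10))
  write_audio(clip, p)
  r <- read_audio(p, duration_bounds_s = c(0, 10))
  expect_equal(max(r$samples), 32767 / 32768, tolerance = 1e-6)

  # 2 s clip against 8-12 s bounds -> flagged, not an error
  clip2 <- audio_clip(sin(2 * pi * 100 * seq(0, 2, by = 1 / fs)), fs,
                      duration_bounds_s = c(0, 100))
  write_audio(clip2, p)
  r2 <- read_audio(p)   # default bounds 8-12 s
  expect_true(r2$duration_flag)
})

test_that("stereo L=0.5, R=-0.5 averages to zero", {
  fs <- 8000
  p <- withr::local_tempfile(fileext = ".wav")
  n <- fs
  # write a stereo PCM16 WAV by hand
  con <- file(p, "wb")
  data_bytes <- n * 2L * 2L
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")   # PCM
  writeBin(2L, con, size = 2, endian = "little")   # stereo
  writeBin(as.integer(fs), con, size = 4, endian = "little")
  writeBin(as.integer(fs * 4), con, size = 4, endian = "little")
  writeBin(4L, con, size = 2, endian = "little")
  writeBin(16L, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_bytes), con, size = 4, endian = "little")
  frames <- rbind(rep(16384L, n), rep(-16384L, n))
  writeBin(as.integer(frames), con, size = 2, endian = "little")
  close(con)
  r <- read_audio(p, duration_bounds_s = c(0, 10))
  expect_true(all(abs(r$samples) < 1e-9))
})

test_that("non-WAV input is a format error", {
  p <- withr::local_tempfile(fileext = ".wav")
  writeLines("this is not audio", p)
  expect_error(read_audio(p), "WAV|RIFF", ignore.case = TRUE)
})

test_that("audio round-trip is accurate to 16-bit quantization", {
  clip <- synth_voice(class_effect_profiles()$control, duration_s = 1,
                      seed = 4, f0_hz = 120)
  p <- withr::local_tempfile(fileext = ".wav")
  write_audio(clip, p)
  r <- read_audio(p, duration_bounds_s = c(0, 10))
  expect_equal(r$samples, clip$samples, tolerance = 1e-4)
  expect_equal(r$sample_rate_hz, clip$sample_rate_hz)
})

test_that("single-trial selection is deterministic and uniform", {
  rec <- participant_record("P1", 55, "female", FALSE, "PD",
                            trial_refs = list(gait = as.list(letters[1:4])))
  picks <- vapply(1:2000, function(s)
    select_single_trial(list(rec), seed = s)[[1]]$trial_refs$gait[[1]],
    character(1))
  expect_true(all(abs(table(picks) / 2000 - 0.25) < 0.04))
  # determinism
  a <- select_single_trial(list(rec), seed = 42)
  b <- select_single_trial(list(rec), seed = 42)
  expect_identical(a, b)
  # single trial kept regardless of seed
  rec1 <- participant_record("P2", 60, "male", TRUE, "control",
                             trial_refs = list(gait = list("only")))
  expect_equal(select_single_trial(list(rec1), seed = 7)[[1]]$trial_refs$gait[[1]],
               "only")
})

test_that("assemble_cohort keeps complete cases, stratifies, and hits 164/30", {
  set.seed(99)
  recs <- lapply(1:194, function(i) {
    participant_record(sprintf("P%03d", i), 50, "male", FALSE,
                       label = if (i <= 97) "PD" else "control",
                       trial_refs = list(gait = list("g"), tapping = list("t"),
                                         voice = list("v")))
  })
  co <- assemble_cohort(recs, train_n = 164, test_n = 30, seed = 1)
  expect_equal(sum(co$split$split == "train"), 164)
  expect_equal(sum(co$split$split == "test"), 30)
  # stratification: class proportions preserved within 1 participant
  tab <- table(co$split$label, co$split$split)
  expect_true(abs(tab["PD", "train"] - 164 * 0.5) <= 1)

  # missing voice trial -> excluded and logged
  recs[[1]]$trial_refs$voice <- list()
  co2 <- assemble_cohort(recs, train_n = 160, test_n = 33, seed = 1)
  expect_equal(nrow(co2$split), 193)
  expect_equal(co2$excluded[[1]]$participant_id, "P001")
  expect_true("voice" %in% co2$excluded[[1]]$missing)
})

test_that("assemble_cohort errors with fewer than 2 per class", {
  recs <- lapply(1:3, function(i)
    participant_record(paste0("P", i), 50, "male", FALSE,
                       label = if (i == 1) "PD" else "control",
                       trial_refs = list(gait = list("g"), tapping = list("t"),
                                         voice = list("v"))))
  expect_error(assemble_cohort(recs, train_n = 2, test_n = 1), "class")
})
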