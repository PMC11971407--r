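# Readers, validators and cohort assembly for the four modality formats:
# tri-axial accelerometer traces (CSV or JSON records), tap-event streams,
# sustained-phonation WAV audio, and the per-participant demographics table.

#' Construct a validated accelerometer trace
#'
#' A trace holds a uniformly sampled tri-axial acceleration time series.
#' Irregular timestamps are resampled onto a uniform grid by linear
#' interpolation at the (lower-)median inter-sample interval, because the
#' FFT-domain gait features require a uniform grid.  The time origin is
#' shifted so the first sample is at t = 0: only relative timing matters
#' to every downstream feature.
#'
#' @param timestamps numeric, seconds, monotone non-decreasing, length >= 2.
#' @param x,y,z acceleration per axis, same length as `timestamps`.
#' @param unit unit the axes are expressed in (`"g"` or `"m/s2"`); recorded
#'   but never converted — all downstream features are scale-covariant and
#'   later standardized.
#' @param source_activity `"gait"` or `"tapping"`.
#' @return object of class `accel_trace` with fields `timestamps`, `x`,
#'   `y`, `z`, `sample_rate_hz`, `unit`, `source_activity`.
#' @export
accel_trace <- function(timestamps, x, y, z, unit = "g",
                        source_activity = c("gait", "tapping")) {
  source_activity <- match.arg(source_activity)
  n <- length(timestamps)
  if (n < 2L) stop("accelerometer trace needs at least 2 samples", call. = FALSE)
  if (length(x) != n || length(y) != n || length(z) != n) {
    stop("timestamps, x, y, z must have equal length", call. = FALSE)
  }
  if (anyNA(timestamps) || anyNA(x) || anyNA(y) || anyNA(z)) {
    stop("accelerometer trace contains NA values", call. = FALSE)
  }
  if (is.unsorted(timestamps)) stop("timestamps must be non-decreasing", call. = FALSE)

  timestamps <- timestamps - timestamps[1L]
  dts <- diff(timestamps)
  if (any(dts <= 0)) {
    keep <- c(TRUE, dts > 0)
    timestamps <- timestamps[keep]; x <- x[keep]; y <- y[keep]; z <- z[keep]
    dts <- diff(timestamps)
    if (length(timestamps) < 2L) stop("fewer than 2 distinct timestamps", call. = FALSE)
  }
  # lower median keeps the modal device interval when a minority of gaps
  # are dropped-sample artifacts
  dt <- as.numeric(quantile(dts, 0.5, type = 1, names = FALSE))
  uniform <- max(dts) - min(dts) < 1e-9 * max(dt, 1e-12)
  if (!uniform) {
    grid <- seq(0, timestamps[length(timestamps)] + dt / 2, by = dt)
    grid <- grid[grid <= timestamps[length(timestamps)] + 1e-12]
    x <- approx(timestamps, x, xout = grid, rule = 2)$y
    y <- approx(timestamps, y, xout = grid, rule = 2)$y
    z <- approx(timestamps, z, xout = grid, rule = 2)$y
    timestamps <- grid
  }
  structure(list(
    timestamps = timestamps, x = x, y = y, z = z,
    sample_rate_hz = 1 / dt, unit = unit, source_activity = source_activity
  ), class = "accel_trace")
}

#' Read an accelerometer trace from CSV or JSON records
#'
#' @param path file path (or connection) to read.
#' @param dialect `"csv"` expects a header `t,x,y,z` (or
#'   `timestamp,x,y,z`); `"json_records"` expects a JSON array of objects
#'   with fields `timestamp`, `x`, `y`, `z`.
#' @param unit,source_activity passed to [accel_trace()].
#' @return an `accel_trace`.
#' @export
read_accel_trace <- function(path, dialect = c("csv", "json_records"),
                             unit = "g", source_activity = "gait") {
  dialect <- match.arg(dialect)
  if (dialect == "csv") {
    df <- read.csv(path, stringsAsFactors = FALSE)
    names(df) <- sub("^timestamp$", "t", tolower(names(df)))
    req <- c("t", "x", "y", "z")
    if (!all(req %in% names(df))) {
      stop("accelerometer CSV must have columns t (or timestamp), x, y, z",
           call. = FALSE)
    }
    for (cn in req) {
      bad <- which(!is.finite(df[[cn]]))
      if (length(bad)) {
        stop(sprintf("malformed accelerometer row: non-finite `%s` at line %d",
                     cn, bad[1L]), call. = FALSE)
      }
    }
  } else {
    df <- jsonlite::fromJSON(path)
    names(df) <- sub("^timestamp$", "t", tolower(names(df)))
    if (!all(c("t", "x", "y", "z") %in% names(df))) {
      stop("JSON records must have fields timestamp, x, y, z", call. = FALSE)
    }
    for (cn in c("t", "x", "y", "z")) {
      bad <- which(!is.finite(df[[cn]]))
      if (length(bad)) {
        stop(sprintf("malformed accelerometer record: non-finite `%s` at record %d",
                     cn, bad[1L]), call. = FALSE)
      }
    }
  }
  if (nrow(df) < 2L) stop("insufficient data: fewer than 2 samples", call. = FALSE)
  accel_trace(df$t, df$x, df$y, df$z, unit = unit,
              source_activity = source_activity)
}

#' Write an accelerometer trace as CSV
#' @param trace an `accel_trace`.
#' @param path output file.
#' @export
write_accel_trace <- function(trace, path) {
  write.csv(data.frame(t = trace$timestamps, x = trace$x, y = trace$y,
                       z = trace$z),
            path, row.names = FALSE)
  invisible(path)
}

#' Construct a validated tap-event series
#'
#' @param times event times in seconds.
#' @param buttons `"left"` / `"right"` per event.
#' @param window_seconds duration of the tapping test (default 20 s).
#' @return object of class `tap_events` with sorted events; events after
#'   the window are dropped and counted in `n_dropped`; an empty series is
#'   valid and carries `empty = TRUE`.
#' @export
tap_events <- function(times, buttons, window_seconds = 20) {
  if (length(times) != length(buttons)) {
    stop("times and buttons must have equal length", call. = FALSE)
  }
  buttons <- tolower(as.character(buttons))
  buttons[buttons %in% c("l")] <- "left"
  buttons[buttons %in% c("r")] <- "right"
  bad <- setdiff(unique(buttons), c("left", "right"))
  if (length(bad)) {
    stop(sprintf("unknown button label(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  ord <- order(times)
  times <- times[ord]; buttons <- buttons[ord]
  keep <- times >= 0 & times <= window_seconds
  n_dropped <- sum(!keep)
  structure(list(
    times = times[keep], buttons = buttons[keep],
    window_seconds = window_seconds, n_dropped = n_dropped,
    empty = sum(keep) == 0L
  ), class = "tap_events")
}

#' Read tap events from CSV or JSON records
#'
#' Expects fields `timestamp` (or `t`) and `button` with values
#' left/right (or l/r).
#'
#' @inheritParams read_accel_trace
#' @param window_seconds test window; later events are dropped with a count.
#' @return a `tap_events` series.
#' @export
read_tap_events <- function(path, dialect = c("csv", "json_records"),
                            window_seconds = 20) {
  dialect <- match.arg(dialect)
  df <- if (dialect == "csv") read.csv(path, stringsAsFactors = FALSE)
        else jsonlite::fromJSON(path)
  names(df) <- sub("^timestamp$", "t", tolower(names(df)))
  if (!all(c("t", "button") %in% names(df))) {
    stop("tap stream must have fields timestamp (or t) and button", call. = FALSE)
  }
  tap_events(df$t, df$button, window_seconds = window_seconds)
}

#' Write tap events as CSV
#' @param taps a `tap_events` series.
#' @param path output file.
#' @export
write_tap_events <- function(taps, path) {
  write.csv(data.frame(t = taps$times, button = taps$buttons),
            path, row.names = FALSE)
  invisible(path)
}

#' Construct a validated audio clip
#'
#' @param samples mono waveform, amplitudes nominally in \[-1, 1\].
#' @param sample_rate_hz sampling rate.
#' @param duration_bounds_s accepted duration range for the sustained-vowel
#'   task; a clip outside the bounds is returned with
#'   `duration_flag = TRUE`, not rejected.
#' @return object of class `audio_clip`.
#' @export
audio_clip <- function(samples, sample_rate_hz,
                       duration_bounds_s = c(8, 12)) {
  if (!is.numeric(samples) || length(samples) < 1L) {
    stop("samples must be a non-empty numeric vector", call. = FALSE)
  }
  if (anyNA(samples)) stop("audio clip contains NA samples", call. = FALSE)
  dur <- length(samples) / sample_rate_hz
  structure(list(
    samples = as.numeric(samples),
    sample_rate_hz = sample_rate_hz,
    duration_s = dur,
    duration_flag = dur < duration_bounds_s[1L] || dur > duration_bounds_s[2L]
  ), class = "audio_clip")
}

#' Read a PCM WAV file
#'
#' Supports 16- and 24-bit integer PCM, mono or stereo; stereo channels are
#' averaged to mono and integer samples scaled to \[-1, 1\] (16-bit
#' full-scale 32767 maps to 32767/32768).
#'
#' @param path WAV file path.
#' @param duration_bounds_s passed to [audio_clip()].
#' @return an `audio_clip`.
#' @export
read_audio <- function(path, duration_bounds_s = c(8, 12)) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF/WAV file", call. = FALSE)
  invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAV container", call. = FALSE)

  fmt <- NULL; data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    sz <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      body <- readBin(con, "raw", sz)
      fmt <- list(
        audio_format = sum(as.integer(body[1:2]) * c(1, 256)),
        n_channels   = sum(as.integer(body[3:4]) * c(1, 256)),
        sample_rate  = sum(as.integer(body[5:8]) * c(1, 256, 65536, 16777216)),
        bits         = sum(as.integer(body[15:16]) * c(1, 256))
      )
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", sz)
    } else {
      invisible(readBin(con, "raw", sz))
    }
    if (sz %% 2L == 1L) invisible(readBin(con, "raw", 1))
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) stop("WAV missing fmt or data chunk", call. = FALSE)
  if (fmt$audio_format != 1L) stop("only integer PCM WAV is supported", call. = FALSE)

  if (fmt$bits == 16L) {
    ints <- readBin(data_raw, "integer", n = length(data_raw) / 2L,
                    size = 2, signed = TRUE, endian = "little")
    s <- ints / 32768
  } else if (fmt$bits == 24L) {
    b <- as.integer(data_raw)
    n <- length(b) %/% 3L
    idx <- seq_len(n)
    v <- b[3L * idx - 2L] + 256L * b[3L * idx - 1L] + 65536L * b[3L * idx]
    v <- ifelse(v >= 8388608, v - 16777216, v)
    s <- v / 8388608
  } else {
    stop(sprintf("unsupported PCM bit depth: %d", fmt$bits), call. = FALSE)
  }
  if (fmt$n_channels == 2L) {
    s <- (s[seq(1, length(s), by = 2)] + s[seq(2, length(s), by = 2)]) / 2
  } else if (fmt$n_channels != 1L) {
    stop("only mono or stereo WAV is supported", call. = FALSE)
  }
  audio_clip(s, fmt$sample_rate, duration_bounds_s = duration_bounds_s)
}

#' Write a mono clip as 16-bit PCM WAV
#'
#' Samples are clipped to \[-1, 1 - 2^-15\] and quantized to 16-bit.
#'
#' @param clip an `audio_clip` (or numeric vector with `sample_rate_hz`).
#' @param path output file.
#' @param sample_rate_hz required if `clip` is a bare numeric vector.
#' @export
write_audio <- function(clip, path, sample_rate_hz = NULL) {
  if (inherits(clip, "audio_clip")) {
    s <- clip$samples; fs <- clip$sample_rate_hz
  } else {
    s <- as.numeric(clip); fs <- sample_rate_hz
    if (is.null(fs)) stop("sample_rate_hz required for a bare vector", call. = FALSE)
  }
  ints <- as.integer(round(pmax(pmin(s, 32767 / 32768), -1) * 32768))
  con <- file(path, "wb")
  on.exit(close(con))
  data_size <- 2L * length(ints)
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_size), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")   # PCM
  writeBin(1L, con, size = 2, endian = "little")   # mono
  writeBin(as.integer(fs), con, size = 4, endian = "little")
  writeBin(as.integer(fs * 2L), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")   # block align
  writeBin(16L, con, size = 2, endian = "little")  # bits
  writeChar("data", con, eos = NULL)
  writeBin(data_size, con, size = 4, endian = "little")
  writeBin(ints, con, size = 2, endian = "little")
  invisible(path)
}

#' Construct a participant record
#'
#' @param participant_id opaque identifier.
#' @param age years (> 0).
#' @param gender `"male"` / `"female"` (coded 0/1 downstream).
#' @param smoker logical.
#' @param label `"PD"`, `"control"`, or `NA` for unlabeled records.
#' @param trial_refs named list mapping activity (`gait`, `tapping`,
#'   `voice`) to a vector of trial references (file paths or in-memory
#'   objects wrapped in a list).
#' @return object of class `participant_record`.
#' @export
participant_record <- function(participant_id, age, gender, smoker,
                               label = NA_character_, trial_refs = list()) {
  if (!is.na(age) && age <= 0) stop("age must be positive", call. = FALSE)
  if (!is.na(label) && !label %in% c("PD", "control")) {
    stop('label must be "PD", "control" or NA', call. = FALSE)
  }
  structure(list(
    participant_id = as.character(participant_id), age = age,
    gender = gender, smoker = isTRUE(smoker), label = label,
    trial_refs = trial_refs
  ), class = "participant_record")
}

#' Keep one uniformly random trial per participant per activity
#'
#' Participants often repeat the same test; keeping a single random trial
#' prevents heavy repeaters from dominating the model.  Selection is a
#' pure function of the seed and the participant id, so reordering the
#' input does not change which trial a participant keeps.
#'
#' @param records list of `participant_record`s.
#' @param seed integer seed.
#' @return the records with every activity's trial list reduced to at most
#'   one element.
#' @export
select_single_trial <- function(records, seed = 1L) {
  lapply(records, function(rec) {
    acts <- names(rec$trial_refs)
    rec$trial_refs <- setNames(lapply(acts, function(act) {
      refs <- rec$trial_refs[[act]]
      if (length(refs) <= 1L) return(refs)
      set.seed(child_seed(seed, paste0(rec$participant_id, "/", act)))
      refs[sample.int(length(refs), 1L)]
    }), acts)
    rec
  })
}

#' Assemble a complete-case cohort with a stratified train/test split
#'
#' Participants missing any of the three activity trials (or a label) are
#' excluded.  The split is stratified by diagnosis so both classes are
#' represented proportionally in train and test.
#'
#' @param records list of `participant_record`s (after
#'   [select_single_trial()]).
#' @param train_n,test_n explicit split sizes (default 164/30, scaled
#'   proportionally when fewer complete cases are available); alternatively
#'   give `train_fraction`.
#' @param train_fraction used when `train_n` is `NULL`.
#' @param seed integer seed for the stratified shuffle (fixed default so
#'   repeated assemblies of the same records agree).
#' @return object of class `cohort_table`: list with `records` (complete
#'   cases), `split` (data.frame: participant_id, label, split), and
#'   `excluded` (ids dropped with the missing activity).
#' @export
assemble_cohort <- function(records, train_n = NULL, test_n = NULL,
                            train_fraction = NULL, seed = 20250404L) {
  required <- c("gait", "tapping", "voice")
  complete <- vapply(records, function(r) {
    all(vapply(required, function(a) length(r$trial_refs[[a]] %||% list()) >= 1L,
               logical(1))) && !is.na(r$label)
  }, logical(1))
  excluded <- lapply(records[!complete], function(r) {
    missing <- required[vapply(required, function(a)
      length(r$trial_refs[[a]] %||% list()) < 1L, logical(1))]
    list(participant_id = r$participant_id,
         missing = if (length(missing)) missing else "label")
  })
  records <- records[complete]
  ids <- vapply(records, `[[`, character(1), "participant_id")
  if (anyDuplicated(ids)) stop("participant ids must be unique", call. = FALSE)
  labels <- vapply(records, `[[`, character(1), "label")
  if (min(table(labels)) < 2L || length(unique(labels)) < 2L) {
    stop("need at least 2 complete-case participants per class", call. = FALSE)
  }
  n <- length(records)
  if (is.null(train_n)) {
    frac <- train_fraction %||% (164 / 194)
    train_n <- round(n * frac)
  } else if (!is.null(test_n) && train_n + test_n > n) {
    # scale the requested sizes down proportionally to what is available
    frac <- train_n / (train_n + test_n)
    train_n <- round(n * frac)
  }
  split <- rep("test", n)
  set.seed(child_seed(seed, "cohort-split"))
  remaining <- train_n
  labs <- sort(unique(labels))
  alloc <- integer(length(labs)); names(alloc) <- labs
  for (lb in labs) alloc[lb] <- round(train_n * sum(labels == lb) / n)
  # fix rounding so the train size is exact
  diffn <- train_n - sum(alloc)
  if (diffn != 0) alloc[which.max(table(labels)[labs])] <-
      alloc[which.max(table(labels)[labs])] + diffn
  for (lb in labs) {
    idx <- which(labels == lb)
    take <- idx[sample.int(length(idx), min(alloc[lb], length(idx)))]
    split[take] <- "train"
  }
  structure(list(
    records = records,
    split = data.frame(participant_id = ids, label = labels, split = split,
                       stringsAsFactors = FALSE),
    excluded = excluded
  ), class = "cohort_table")
}

#' @export
print.cohort_table <- function(x, ...) {
  tab <- table(x$split$label, x$split$split)
  cat(sprintf("Cohort: %d complete-case participants (%d excluded)\n",
              nrow(x$split), length(x$excluded)))
  print(tab)
  invisible(x)
}
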