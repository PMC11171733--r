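#' Simulation settings for the synthetic apneic-ECG generator
#'
#' Bundles every knob of the synthetic corpus: recording geometry, heart-rate
#' dynamics, event scheduling, and signal-level nuisance terms. The defaults
#' describe a desk-scale study corpus: 80 two-hour recordings at 200 Hz with
#' per-recording event rates spanning the clinically relevant AHI range
#' (5-60 events/h) and event durations of 12-40 s, i.e. mostly the 10-20 s
#' regime typical of scored sleep-breathing events.
#'
#' During each event the R-R interval (RRI) lengthens by the class's
#' modulation depth (relative bradycardia under apnea) and rebounds with a
#' tachycardic dip for ~10 s after the event ends; R-peak amplitudes carry a
#' respiration-frequency oscillation that is suppressed during events and
#' transiently amplified afterwards (post-event hyperventilation). Hypopnea
#' uses the same envelope at half depth, making it the harder class by
#' construction.
#'
#' @param n_recordings number of recordings in a corpus.
#' @param duration_s length of each recording in seconds.
#' @param fs ECG sampling rate in Hz.
#' @param base_hr_bpm mean heart rate (beats per minute).
#' @param event_rate_per_h length-2 range; each recording draws its own event
#'   rate uniformly from this interval (events/hour). A scalar is recycled to
#'   a degenerate range.
#' @param duration_range_s length-2 range of event durations in seconds;
#'   the lower bound must be >= 10 (the scoring definition of an event).
#' @param hypopnea_fraction probability that an event is a hypopnea.
#' @param modulation_depth_apnea,modulation_depth_hypopnea peak fractional RRI
#'   lengthening during an event of each class; hypopnea must be shallower.
#' @param rr_jitter_sd per-beat Gaussian RR variability (seconds).
#' @param resp_mod baseline fractional R-peak amplitude oscillation.
#' @param resp_freq_hz respiration frequency driving the amplitude oscillation.
#' @param noise_sd additive broadband noise amplitude (mV).
#' @param wander_amp,wander_freq_hz sinusoidal baseline wander (mV, Hz).
#' @param min_gap_s minimum gap between consecutive events (seconds).
#' @param seed master integer seed; every recording derives its own stream.
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_recordings = 80L,
                       duration_s = 7200,
                       fs = 200,
                       base_hr_bpm = 70,
                       event_rate_per_h = c(5, 60),
                       duration_range_s = c(12, 40),
                       hypopnea_fraction = 0.35,
                       modulation_depth_apnea = 0.25,
                       modulation_depth_hypopnea = 0.125,
                       rr_jitter_sd = 0.02,
                       resp_mod = 0.05,
                       resp_freq_hz = 0.25,
                       noise_sd = 0.05,
                       wander_amp = 0.2,
                       wander_freq_hz = 0.2,
                       min_gap_s = 10,
                       seed = 1L) {
  if (length(event_rate_per_h) == 1L) {
    event_rate_per_h <- rep(event_rate_per_h, 2L)
  }
  cfg <- list(
    n_recordings = as.integer(n_recordings), duration_s = duration_s, fs = fs,
    base_hr_bpm = base_hr_bpm, event_rate_per_h = event_rate_per_h,
    duration_range_s = duration_range_s,
    hypopnea_fraction = hypopnea_fraction,
    modulation_depth_apnea = modulation_depth_apnea,
    modulation_depth_hypopnea = modulation_depth_hypopnea,
    rr_jitter_sd = rr_jitter_sd, resp_mod = resp_mod,
    resp_freq_hz = resp_freq_hz, noise_sd = noise_sd,
    wander_amp = wander_amp, wander_freq_hz = wander_freq_hz,
    min_gap_s = min_gap_s, seed = as.integer(seed)
  )
  stopifnot(
    cfg$n_recordings >= 1L, cfg$duration_s > 0, cfg$fs > 0,
    cfg$base_hr_bpm > 0,
    length(cfg$event_rate_per_h) == 2L,
    cfg$event_rate_per_h[1] >= 0,
    diff(cfg$event_rate_per_h) >= 0,
    length(cfg$duration_range_s) == 2L,
    cfg$duration_range_s[1] >= 10,
    diff(cfg$duration_range_s) >= 0,
    cfg$hypopnea_fraction >= 0, cfg$hypopnea_fraction <= 1,
    cfg$modulation_depth_hypopnea < cfg$modulation_depth_apnea,
    cfg$rr_jitter_sd >= 0, cfg$noise_sd >= 0, cfg$wander_amp >= 0,
    cfg$min_gap_s >= 0
  )
  class(cfg) <- "sim_config"
  cfg
}

#' Draw a non-overlapping sleep-breathing-event schedule
#'
#' Places apnea/hypopnea events sequentially along a recording: each
#' inter-event gap is the minimum gap plus an exponential slack chosen so the
#' expected onset-to-onset spacing matches the requested event rate, and each
#' duration is drawn uniformly from the configured range. Events that would
#' extend past the end of the recording are discarded, so all returned events
#' lie fully inside `[0, duration_s)`.
#'
#' Uses the current RNG state; callers wanting reproducibility seed first.
#'
#' @param duration_s recording length in seconds.
#' @param cfg a [sim_config()].
#' @param rate_per_h optional fixed event rate; by default one draw from
#'   `cfg$event_rate_per_h`.
#' @return a data frame of class `annotation_events` with columns
#'   `kind` ("apnea"/"hypopnea"), `start_s`, `duration_s`, sorted by start.
#' @export
generate_event_schedule <- function(duration_s, cfg, rate_per_h = NULL) {
  stopifnot(duration_s > 0)
  if (is.null(rate_per_h)) {
    rate_per_h <- runif(1, cfg$event_rate_per_h[1], cfg$event_rate_per_h[2])
  }
  if (rate_per_h <= 0) {
    return(empty_events())
  }
  mean_dur <- mean(cfg$duration_range_s)
  cycle_s <- 3600 / rate_per_h
  slack <- cycle_s - mean_dur - cfg$min_gap_s
  if (slack <= 0) {
    stop("infeasible event density: rate ", round(rate_per_h, 1),
         "/h with mean duration ", mean_dur, " s and minimum gap ",
         cfg$min_gap_s, " s exceeds recording capacity")
  }
  starts <- numeric(0)
  durs <- numeric(0)
  # first onset gets no structural gap, only the exponential slack
  t <- rexp(1, rate = 1 / slack)
  repeat {
    d <- runif(1, cfg$duration_range_s[1], cfg$duration_range_s[2])
    if (t + d > duration_s) break
    starts <- c(starts, t)
    durs <- c(durs, d)
    t <- t + d + cfg$min_gap_s + rexp(1, rate = 1 / slack)
    if (t >= duration_s) break
  }
  n <- length(starts)
  kind <- ifelse(rbinom(n, 1L, cfg$hypopnea_fraction) == 1L,
                 "hypopnea", "apnea")
  ev <- data.frame(kind = kind, start_s = starts, duration_s = durs,
                   stringsAsFactors = FALSE)
  class(ev) <- c("annotation_events", "data.frame")
  validate_events(ev)
  ev
}

empty_events <- function() {
  ev <- data.frame(kind = character(0), start_s = numeric(0),
                   duration_s = numeric(0), stringsAsFactors = FALSE)
  class(ev) <- c("annotation_events", "data.frame")
  ev
}

#' Validate an annotation event table
#'
#' Checks the invariants every downstream stage relies on: durations >= 10 s,
#' non-negative starts, sorted and pairwise non-overlapping events.
#'
#' @param events a data frame with columns `kind`, `start_s`, `duration_s`.
#' @return the events, invisibly; errors otherwise.
#' @export
validate_events <- function(events) {
  stopifnot(all(c("kind", "start_s", "duration_s") %in% names(events)))
  if (nrow(events) == 0L) return(invisible(events))
  if (any(events$duration_s < 10)) {
    stop("annotation corrupt: event duration below 10 s")
  }
  if (any(events$start_s < 0)) stop("annotation corrupt: negative start time")
  if (is.unsorted(events$start_s, strictly = FALSE)) {
    stop("annotation corrupt: events not sorted by start time")
  }
  ends <- events$start_s + events$duration_s
  if (nrow(events) > 1L && any(events$start_s[-1L] < ends[-nrow(events)])) {
    stop("annotation corrupt: overlapping events")
  }
  invisible(events)
}

# Event-locked fractional RRI modulation evaluated at vector `t_s`.
# Raised-cosine-edged trapezoid of the class depth over each event, followed
# by a half-depth rebound dip over the 10 s after the event ends.
rr_modulation <- function(t_s, events, cfg) {
  m <- numeric(length(t_s))
  if (nrow(events) == 0L) return(m)
  depth <- ifelse(events$kind == "hypopnea",
                  cfg$modulation_depth_hypopnea, cfg$modulation_depth_apnea)
  for (i in seq_len(nrow(events))) {
    s <- events$start_s[i]; d <- events$duration_s[i]
    ramp <- min(5, d / 4)
    u <- t_s - s
    inside <- u >= 0 & u < d
    if (any(inside)) {
      ui <- u[inside]
      env <- rep(1, length(ui))
      env[ui < ramp] <- 0.5 * (1 - cos(pi * ui[ui < ramp] / ramp))
      tailu <- d - ui
      env[tailu < ramp] <- 0.5 * (1 - cos(pi * tailu[tailu < ramp] / ramp))
      m[inside] <- m[inside] + depth[i] * env
    }
    post <- u >= d & u < d + 10
    if (any(post)) {
      v <- (u[post] - d) / 10
      m[post] <- m[post] - 0.5 * depth[i] * 0.5 * (1 - cos(2 * pi * v))
    }
  }
  m
}

# 0..1 event envelope (class-independent) used for amplitude shaping.
event_envelope <- function(t_s, events) {
  e <- numeric(length(t_s))
  for (i in seq_len(nrow(events))) {
    s <- events$start_s[i]; d <- events$duration_s[i]
    u <- t_s - s
    e[u >= 0 & u < d] <- 1
  }
  e
}

# 0..1 post-event envelope over the 10 s following each event.
post_event_envelope <- function(t_s, events) {
  e <- numeric(length(t_s))
  for (i in seq_len(nrow(events))) {
    endt <- events$start_s[i] + events$duration_s[i]
    u <- t_s - endt
    sel <- u >= 0 & u < 10
    e[sel] <- pmax(e[sel], sin(pi * u[sel] / 10))
  }
  e
}

#' Generate an event-modulated RR tachogram
#'
#' Produces beat times, the RR interval following each beat, and the beat's
#' R-peak amplitude. Baseline RR is `60 / base_hr_bpm` with Gaussian per-beat
#' jitter; events impose the cyclic bradycardia-tachycardia variation
#' described in [sim_config()]. Beat amplitudes oscillate at the respiration
#' frequency; the oscillation is damped during events and boosted for ~10 s
#' afterwards.
#'
#' @param duration_s recording length in seconds.
#' @param events an `annotation_events` table (may be empty).
#' @param cfg a [sim_config()].
#' @return data frame with columns `time_s` (beat onset), `rr_s` (interval to
#'   the next beat) and `amp_mv`.
#' @export
generate_rr_tachogram <- function(duration_s, events, cfg) {
  validate_events(events)
  rr0 <- 60 / cfg$base_hr_bpm
  # precomputed modulation lookup on a fine grid keeps the beat loop cheap
  dt <- 0.25
  grid <- seq(0, duration_s + dt, by = dt)
  mod_grid <- rr_modulation(grid, events, cfg)
  n_max <- ceiling(duration_s / (rr0 * 0.5)) + 2L
  times <- numeric(n_max)
  rrs <- numeric(n_max)
  jit <- rnorm(n_max, 0, cfg$rr_jitter_sd)
  t <- 0
  k <- 0L
  while (t < duration_s) {
    k <- k + 1L
    m <- mod_grid[floor(t / dt) + 1L]
    rr <- rr0 * (1 + m) + jit[k]
    rr <- min(max(rr, 0.3), 3)
    times[k] <- t
    rrs[k] <- rr
    t <- t + rr
  }
  times <- times[seq_len(k)]
  rrs <- rrs[seq_len(k)]
  env <- event_envelope(times, events)
  post <- post_event_envelope(times, events)
  mod_amp <- cfg$resp_mod * (1 - 0.8 * env + 2 * post)
  amps <- 1 + mod_amp * sin(2 * pi * cfg$resp_freq_hz * times)
  data.frame(time_s = times, rr_s = rrs, amp_mv = amps)
}

# Biphasic QRS-like template with unit maximum exactly at its centre sample.
qrs_template <- function(fs, width_s = 0.1) {
  half <- round(width_s / 2 * fs)
  tt <- (-half:half) / fs
  w <- exp(-0.5 * (tt / 0.013)^2) -
    0.35 * exp(-0.5 * ((tt - 0.03) / 0.02)^2) -
    0.25 * exp(-0.5 * ((tt + 0.03) / 0.02)^2)
  w / max(w)
}

#' Synthesize a single-lead ECG waveform from a tachogram
#'
#' Places one amplitude-scaled QRS-like template (narrow biphasic pulse,
#' width ~0.1 s) at each beat time, then adds sinusoidal baseline wander and
#' white Gaussian noise. The R-peak sample of beat k is the template maximum
#' and lands within one sample of `time_s[k] * fs`.
#'
#' @param tachogram output of [generate_rr_tachogram()].
#' @param cfg a [sim_config()].
#' @param duration_s recording length in seconds (defaults to spanning the
#'   tachogram).
#' @param record_id,patient_id identifiers stored on the recording.
#' @return an object of class `ecg_recording`: list with `record_id`,
#'   `patient_id`, `fs` and `samples` (mV).
#' @export
synthesize_ecg <- function(tachogram, cfg, duration_s = NULL,
                           record_id = "rec", patient_id = record_id) {
  tt <- tachogram$time_s
  stopifnot(length(tt) >= 1L, !is.unsorted(tt, strictly = TRUE))
  fs <- cfg$fs
  tmpl <- qrs_template(fs)
  L <- length(tmpl)
  half <- (L - 1L) %/% 2L
  if (length(tt) > 1L && min(diff(tt)) < (L - 1) / fs) {
    stop("beat spacing shorter than the QRS template width")
  }
  if (is.null(duration_s)) duration_s <- max(tt) + 1
  n <- round(duration_s * fs)
  x <- numeric(n + 2L * L)
  centers <- round(tt * fs) + 1L + L  # into the padded vector
  amps <- tachogram$amp_mv
  for (j in seq_len(L)) {
    idx <- centers + (j - 1L) - half
    x[idx] <- x[idx] + tmpl[j] * amps
  }
  x <- x[(L + 1L):(L + n)]
  if (cfg$wander_amp > 0) {
    ts <- (seq_len(n) - 1L) / fs
    x <- x + cfg$wander_amp * sin(2 * pi * cfg$wander_freq_hz * ts)
  }
  if (cfg$noise_sd > 0) x <- x + rnorm(n, 0, cfg$noise_sd)
  new_ecg_recording(record_id, patient_id, fs, x)
}

new_ecg_recording <- function(record_id, patient_id, fs, samples) {
  structure(list(record_id = record_id, patient_id = patient_id,
                 fs = fs, samples = as.numeric(samples)),
            class = "ecg_recording")
}

#' @export
print.ecg_recording <- function(x, ...) {
  cat("<ecg_recording>", x$record_id, "patient", x$patient_id, "\n")
  cat(sprintf("  %d samples at %g Hz (%.1f s)\n",
              length(x$samples), x$fs, length(x$samples) / x$fs))
  invisible(x)
}

#' Simulate one annotated recording
#'
#' Seeds a per-recording RNG stream from the master seed, draws an event
#' schedule, tachogram and waveform, and returns all three.
#'
#' @param cfg a [sim_config()].
#' @param index recording index (drives the seed stream and identifiers).
#' @param patient_id optional patient identifier.
#' @param waveform set `FALSE` to skip tachogram and waveform synthesis
#'   (annotation-only studies).
#' @return list with `ecg` ([synthesize_ecg()] output), `events`, `tachogram`.
#' @export
simulate_recording <- function(cfg, index = 1L, patient_id = NULL,
                               waveform = TRUE) {
  set.seed(derive_seed(cfg$seed, index))
  record_id <- sprintf("rec%04d", index)
  if (is.null(patient_id)) patient_id <- sprintf("pat%04d", index)
  events <- generate_event_schedule(cfg$duration_s, cfg)
  if (!waveform) {
    return(list(ecg = NULL, events = events, tachogram = NULL,
                record_id = record_id, patient_id = patient_id))
  }
  tach <- generate_rr_tachogram(cfg$duration_s, events, cfg)
  ecg <- synthesize_ecg(tach, cfg, cfg$duration_s, record_id, patient_id)
  list(ecg = ecg, events = events, tachogram = tach,
       record_id = record_id, patient_id = patient_id)
}

# Patient assignment mirrors a corpus where a small share of patients
# contribute two recordings (about 1465 recordings from 1381 patients).
corpus_patient_ids <- function(n_recordings) {
  n_pat <- max(1L, round(n_recordings * 1381 / 1465))
  idx <- ((seq_len(n_recordings) - 1L) %% n_pat) + 1L
  sprintf("pat%04d", idx)
}

#' Simulate a full annotated corpus
#'
#' Generates `cfg$n_recordings` recordings. With `dir = NULL` everything is
#' returned in memory; otherwise each recording is written as a WFDB record
#' (`.hea`/`.dat`), each annotation as a CSV (`kind,start_s,duration_s`), and
#' a JSON manifest maps record ids to patient ids. Fully reproducible from
#' `cfg$seed`.
#'
#' @param cfg a [sim_config()].
#' @param dir output directory, or `NULL` for an in-memory corpus.
#' @param keep_waveform with `dir = NULL`, set `FALSE` to drop waveforms and
#'   keep only events/tachograms (annotation-only studies).
#' @return list with `recordings` (named list or NULL when written to disk),
#'   `events` (named list), `manifest` (named character vector
#'   record_id -> patient_id) and `dir`.
#' @export
simulate_corpus <- function(cfg, dir = NULL, keep_waveform = TRUE) {
  pats <- corpus_patient_ids(cfg$n_recordings)
  manifest <- stats::setNames(pats, sprintf("rec%04d", seq_len(cfg$n_recordings)))
  recs <- list()
  evs <- list()
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  }
  need_wave <- !is.null(dir) || keep_waveform
  for (i in seq_len(cfg$n_recordings)) {
    sim <- simulate_recording(cfg, i, pats[i], waveform = need_wave)
    rid <- sim$record_id
    evs[[rid]] <- sim$events
    if (!is.null(dir)) {
      write_wfdb_record(sim$ecg, dir)
      write_annotations(sim$events, file.path(dir, paste0(rid, "_events.csv")))
    } else if (keep_waveform) {
      recs[[rid]] <- sim$ecg
    }
  }
  if (!is.null(dir)) {
    jsonlite::write_json(as.list(manifest),
                         file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  list(recordings = if (is.null(dir) && keep_waveform) recs else NULL,
       events = evs, manifest = manifest, dir = dir)
}

#' Write / read annotation CSV files
#'
#' The on-disk dialect is a plain CSV with header `kind,start_s,duration_s`.
#' `read_annotations` also accepts a whitespace-delimited text export with
#' the same three columns (event, start, duration).
#'
#' @param events an `annotation_events` table.
#' @param path file path.
#' @return `read_annotations` returns an `annotation_events` data frame.
#' @export
write_annotations <- function(events, path) {
  write.csv(as.data.frame(events)[, c("kind", "start_s", "duration_s")],
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_annotations
#' @export
read_annotations <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl(",", first, fixed = TRUE)) {
    df <- read.csv(path, stringsAsFactors = FALSE)
  } else {
    df <- read.table(path, header = TRUE, stringsAsFactors = FALSE)
    names(df) <- c("kind", "start_s", "duration_s")[seq_along(names(df))]
  }
  names(df)[1] <- "kind"
  df$start_s <- as.numeric(df$start_s)
  df$duration_s <- as.numeric(df$duration_s)
  df <- df[order(df$start_s), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("annotation_events", "data.frame")
  validate_events(df)
  df
}

#' Minimal WFDB single-channel record I/O
#'
#' Writes/reads a WFDB format-16 record: a text header `<id>.hea` and a
#' little-endian 16-bit `.dat` with gain 200 adu/mV. Only the single-channel
#' layout produced by this package is supported.
#'
#' @param ecg an `ecg_recording`.
#' @param dir directory for the record files.
#' @param record path (without extension) or directory + record name.
#' @return `read_wfdb_record` returns an `ecg_recording`.
#' @export
write_wfdb_record <- function(ecg, dir) {
  gain <- 200
  adc <- as.integer(round(pmin(pmax(ecg$samples * gain, -32768), 32767)))
  hea <- file.path(dir, paste0(ecg$record_id, ".hea"))
  dat <- file.path(dir, paste0(ecg$record_id, ".dat"))
  lines <- c(
    sprintf("%s 1 %g %d", ecg$record_id, ecg$fs, length(adc)),
    sprintf("%s.dat 16 %d/mV 16 0 %d 0 0 ECG", ecg$record_id, gain,
            if (length(adc)) adc[1] else 0L),
    sprintf("# patient %s", ecg$patient_id)
  )
  writeLines(lines, hea)
  con <- file(dat, "wb")
  on.exit(close(con))
  writeBin(adc, con, size = 2L, endian = "little")
  invisible(file.path(dir, ecg$record_id))
}

#' @rdname write_wfdb_record
#' @export
read_wfdb_record <- function(record) {
  hea <- paste0(record, ".hea")
  if (!file.exists(hea)) stop("WFDB header not found: ", hea)
  lines <- readLines(hea)
  top <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  record_id <- top[1]
  fs <- as.numeric(top[3])
  n <- as.integer(top[4])
  sig <- strsplit(trimws(lines[2]), "\\s+")[[1]]
  gain <- as.numeric(sub("/.*$", "", sig[3]))
  patient_id <- record_id
  pl <- grep("^# patient ", lines, value = TRUE)
  if (length(pl)) patient_id <- sub("^# patient ", "", pl[1])
  dat <- file.path(dirname(hea), sig[1])
  con <- file(dat, "rb")
  on.exit(close(con))
  adc <- readBin(con, "integer", n = n, size = 2L, endian = "little")
  new_ecg_recording(record_id, patient_id, fs, adc / gain)
}
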