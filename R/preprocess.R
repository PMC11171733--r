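#' Downsample an ECG recording
#'
#' Anti-aliased rate reduction to `target_fs` (default 100 Hz). Integer
#' factors use [signal::decimate()]; non-integer ratios fall back to
#' polyphase [signal::resample()]. A recording already at the target rate is
#' returned unchanged.
#'
#' @param ecg an `ecg_recording`.
#' @param target_fs output sampling rate in Hz.
#' @return an `ecg_recording` at `target_fs`.
#' @export
downsample_ecg <- function(ecg, target_fs = 100) {
  if (target_fs > ecg$fs) stop("target_fs exceeds the recording rate")
  if (target_fs == ecg$fs) return(ecg)
  q <- ecg$fs / target_fs
  if (abs(q - round(q)) < 1e-9) {
    y <- signal::decimate(ecg$samples, round(q))
  } else {
    frac <- rational_ratio(target_fs, ecg$fs)
    y <- signal::resample(ecg$samples, frac[1], frac[2])
  }
  new_ecg_recording(ecg$record_id, ecg$patient_id, target_fs, y)
}

rational_ratio <- function(p, q, max_den = 1000L) {
  for (d in seq_len(max_den)) {
    num <- p / q * d
    if (abs(num - round(num)) < 1e-9) return(c(round(num), d))
  }
  stop("sampling-rate ratio is not a small rational number")
}

#' Bandpass filter an ECG recording
#'
#' Zero-phase 4th-order Butterworth bandpass (applied forward and backward
#' with [signal::filtfilt()]), 3-45 Hz by default, removing baseline wander
#' and high-frequency noise without shifting R-peak times.
#'
#' @param ecg an `ecg_recording`.
#' @param low,high band edges in Hz; must satisfy `0 < low < high < fs/2`.
#' @return a filtered `ecg_recording` of identical length.
#' @export
bandpass_ecg <- function(ecg, low = 3, high = 45) {
  nyq <- ecg$fs / 2
  if (!(low > 0 && low < high)) stop("band edges must satisfy 0 < low < high")
  if (high >= nyq) stop("upper band edge must be below the Nyquist frequency")
  bf <- signal::butter(4, c(low, high) / nyq, type = "pass")
  y <- signal::filtfilt(bf, ecg$samples)
  new_ecg_recording(ecg$record_id, ecg$patient_id, ecg$fs, y)
}

#' Detect R peaks with an adaptive-threshold (Christov-style) scanner
#'
#' Builds a detection envelope (rectified first difference smoothed over
#' 40 ms), then scans it with an adaptive steep-slope threshold that is
#' re-seeded at 60% of each accepted beat's envelope peak (averaged over the
#' last five beats) and decays after a 220 ms refractory period. Each
#' envelope crossing is refined to the local maximum of the filtered ECG
#' within +/-80 ms, whose sample value is the R-peak amplitude. The detector
#' is pluggable: any function returning the same structure can replace it in
#' [preprocess_recording()].
#'
#' @param ecg a filtered `ecg_recording` (typically 100 Hz, 3-45 Hz band).
#' @param min_rr_s minimum separation between accepted peaks in seconds.
#' @return an object of class `peak_train`: list with strictly increasing
#'   `times_s` and matching `amps_mv`.
#' @export
detect_r_peaks <- function(ecg, min_rr_s = 0.25) {
  x <- ecg$samples
  fs <- ecg$fs
  n <- length(x)
  empty <- structure(list(times_s = numeric(0), amps_mv = numeric(0)),
                     class = "peak_train")
  if (n < fs) return(empty)
  d <- abs(c(diff(x), 0))
  w <- max(1L, round(0.04 * fs))
  env <- as.numeric(stats::filter(d, rep(1 / w, w), sides = 2))
  env[is.na(env)] <- 0
  emax <- max(env)
  if (emax <= 0) return(empty)
  init <- 0.5 * max(env[seq_len(min(n, round(5 * fs)))])
  if (init <= 0) init <- 0.5 * emax
  cand <- qrs_scan(env, fs, 0.22, 1.0, init)
  if (length(cand) == 0L) return(empty)
  half <- round(0.08 * fs)
  loc <- integer(length(cand))
  for (i in seq_along(cand)) {
    a <- max(1L, cand[i] - half)
    b <- min(n, cand[i] + half)
    loc[i] <- a + which.max(x[a:b]) - 1L
  }
  # enforce strictly increasing peaks with the minimum RR separation,
  # keeping the larger of two colliding candidates
  keep <- logical(length(loc))
  lastp <- -Inf
  lasti <- 0L
  min_sep <- min_rr_s * fs
  for (i in seq_along(loc)) {
    if (loc[i] - lastp >= min_sep) {
      keep[i] <- TRUE
      lastp <- loc[i]
      lasti <- i
    } else if (lasti > 0L && x[loc[i]] > x[loc[lasti]]) {
      keep[lasti] <- FALSE
      keep[i] <- TRUE
      lastp <- loc[i]
      lasti <- i
    }
  }
  loc <- unique(loc[keep])
  structure(list(times_s = (loc - 1) / fs, amps_mv = x[loc]),
            class = "peak_train")
}

#' @export
print.peak_train <- function(x, ...) {
  cat(sprintf("<peak_train> %d peaks", length(x$times_s)))
  if (length(x$times_s) > 1L) {
    cat(sprintf(", mean RR %.3f s", mean(diff(x$times_s))))
  }
  cat("\n")
  invisible(x)
}

#' Derive RRI and RPA series from a peak train
#'
#' The R-R interval series takes value `times[i+1] - times[i]` timestamped at
#' the later peak; the R-peak amplitude series passes amplitudes through at
#' their own peak times.
#'
#' @param peaks a `peak_train` with at least two peaks.
#' @return list with data frames `rri` and `rpa`, each with `time_s`,
#'   `value` columns (seconds and mV respectively).
#' @export
derive_rri_rpa <- function(peaks) {
  if (length(peaks$times_s) < 2L) {
    stop(insufficient_beats("fewer than two detected peaks"))
  }
  list(
    rri = data.frame(time_s = peaks$times_s[-1L], value = diff(peaks$times_s)),
    rpa = data.frame(time_s = peaks$times_s, value = peaks$amps_mv)
  )
}

#' Resample a derived series onto a fixed-length uniform grid
#'
#' Linear interpolation of `(time_s, value)` evaluated at `n_points`
#' uniformly spaced points over the half-open window `[start_s, end_s)`.
#' Beyond the observed time range the nearest value is replicated
#' (recording-edge policy), so windows that extend before the first or after
#' the last beat remain defined.
#'
#' @param series data frame with `time_s`, `value`.
#' @param window numeric length-2 `(start_s, end_s)`.
#' @param n_points output length (180 for 1-min, 900 for 5-min windows).
#' @return numeric vector of length `n_points`.
#' @export
resample_to_fixed <- function(series, window, n_points) {
  if (is.null(series) || nrow(series) < 2L) {
    stop(insufficient_beats())
  }
  grid <- window[1] + (seq_len(n_points) - 1L) * (window[2] - window[1]) / n_points
  approx(series$time_s, series$value, xout = grid, rule = 2, ties = "ordered")$y
}

# Replace physiologically implausible RR intervals (outside [0.3, 2] s,
# i.e. missed or spurious detections) by the median of plausible intervals
# within +/-30 s, matching the 1-min window scale.
clean_rri_series <- function(rri, lo = 0.3, hi = 2.0) {
  bad <- which(rri$value < lo | rri$value > hi)
  if (length(bad) == 0L) return(rri)
  ok <- rri$value >= lo & rri$value <= hi
  global_med <- if (any(ok)) median(rri$value[ok]) else 1
  v <- rri$value
  for (i in bad) {
    sel <- ok & abs(rri$time_s - rri$time_s[i]) <= 30
    v[i] <- if (any(sel)) median(rri$value[sel]) else global_med
  }
  rri$value <- v
  rri
}

#' Preprocess a raw ECG recording
#'
#' Runs the full conditioning chain: downsample to `target_fs`, zero-phase
#' bandpass, R-peak detection, RRI/RPA derivation and RR-outlier cleaning.
#' The result carries everything [build_window_pair()] and
#' [build_sequences()] need; the waveform itself is dropped.
#'
#' @param ecg an `ecg_recording`.
#' @param target_fs processing rate in Hz.
#' @param band length-2 bandpass edges in Hz.
#' @param detector peak-detection function with the [detect_r_peaks()]
#'   contract.
#' @return an object of class `ecg_prep`.
#' @export
preprocess_recording <- function(ecg, target_fs = 100, band = c(3, 45),
                                 detector = detect_r_peaks) {
  x <- downsample_ecg(ecg, target_fs)
  x <- bandpass_ecg(x, band[1], band[2])
  peaks <- detector(x)
  duration_s <- length(ecg$samples) / ecg$fs
  ok <- length(peaks$times_s) >= 2L
  rri <- NULL
  rpa <- NULL
  if (ok) {
    ser <- derive_rri_rpa(peaks)
    rri <- clean_rri_series(ser$rri)
    rpa <- ser$rpa
  }
  structure(list(
    record_id = ecg$record_id, patient_id = ecg$patient_id,
    fs = target_fs, duration_s = duration_s, peaks = peaks,
    rri = rri, rpa = rpa, ok = ok,
    med_rri = if (ok) median(rri$value) else 1,
    med_rpa = if (ok) median(rpa$value) else 1
  ), class = "ecg_prep")
}

#' @export
print.ecg_prep <- function(x, ...) {
  cat("<ecg_prep>", x$record_id, sprintf("%.1f s,", x$duration_s),
      length(x$peaks$times_s), "peaks\n")
  invisible(x)
}

#' Build the RRI/RPA window pair for one 10-s step
#'
#' Assembles the model input for segment `t` (0-based on the 10-s grid): the
#' 1-min window `[10t-25, 10t+35)` resampled to 2x180 (channels RRI, RPA)
#' and the 5-min window `[10t-145, 10t+155)` resampled to 2x900. Windows
#' reaching past the recording edges are completed by replicating the
#' nearest derived-series value. A recording with fewer than two usable
#' peaks yields median-filled channels and `flag = TRUE`.
#'
#' @param prep an `ecg_prep`.
#' @param t 0-based segment index.
#' @return list with `t`, `r1` (2x180 matrix, rows `rri`/`rpa`), `r5`
#'   (2x900) and logical `flag`.
#' @export
build_window_pair <- function(prep, t) {
  ext <- window_extent(t)
  if (!prep$ok) {
    r1 <- rbind(rri = rep(prep$med_rri, 180), rpa = rep(prep$med_rpa, 180))
    r5 <- rbind(rri = rep(prep$med_rri, 900), rpa = rep(prep$med_rpa, 900))
    return(list(t = t, r1 = r1, r5 = r5, flag = TRUE))
  }
  r1 <- rbind(rri = resample_to_fixed(prep$rri, ext$min1, 180),
              rpa = resample_to_fixed(prep$rpa, ext$min1, 180))
  r5 <- rbind(rri = resample_to_fixed(prep$rri, ext$min5, 900),
              rpa = resample_to_fixed(prep$rpa, ext$min5, 900))
  list(t = t, r1 = r1, r5 = r5, flag = FALSE)
}

# Vectorised construction of all window pairs of a recording: one approx()
# call per channel and scale over the concatenated grids of every segment.
build_all_windows <- function(prep, n_segments) {
  r1 <- array(0, dim = c(2L, 180L, n_segments))
  r5 <- array(0, dim = c(2L, 900L, n_segments))
  if (!prep$ok) {
    r1[1L, , ] <- prep$med_rri; r1[2L, , ] <- prep$med_rpa
    r5[1L, , ] <- prep$med_rri; r5[2L, , ] <- prep$med_rpa
    return(list(r1 = r1, r5 = r5, flags = rep(TRUE, n_segments)))
  }
  t10 <- (seq_len(n_segments) - 1L) * 10
  grid1 <- rep(t10, each = 180L) - 25 + (60 / 180) * (0:179)
  grid5 <- rep(t10, each = 900L) - 145 + (300 / 900) * (0:899)
  interp <- function(ser, xout) {
    approx(ser$time_s, ser$value, xout = xout, rule = 2, ties = "ordered")$y
  }
  r1[1L, , ] <- interp(prep$rri, grid1)
  r1[2L, , ] <- interp(prep$rpa, grid1)
  r5[1L, , ] <- interp(prep$rri, grid5)
  r5[2L, , ] <- interp(prep$rpa, grid5)
  list(r1 = r1, r5 = r5, flags = rep(FALSE, n_segments))
}
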