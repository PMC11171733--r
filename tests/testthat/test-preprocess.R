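test_that("downsampling halves 200 Hz to 100 Hz and preserves tones", {
  x <- sleepahi:::new_ecg_recording("r", "p", 200, rnorm(1200))
  y <- downsample_ecg(x)
  expect_equal(y$fs, 100)
  expect_length(y$samples, 600)

  # identity at the target rate
  z <- sleepahi:::new_ecg_recording("r", "p", 100, rnorm(500))
  expect_identical(downsample_ecg(z), z)

  expect_error(downsample_ecg(z, 200), "exceeds")

  # a 10 Hz tone survives with amplitude within 1% (FFT peak comparison)
  n <- 2000
  tone <- sin(2 * pi * 10 * (0:(n - 1)) / 200)
  y <- downsample_ecg(sleepahi:::new_ecg_recording("r", "p", 200, tone))
  amp_in <- 2 * max(Mod(fft(tone))) / n
  amp_out <- 2 * max(Mod(fft(y$samples))) / length(y$samples)
  expect_lt(abs(amp_out - amp_in) / amp_in, 0.01)
})

test_that("bandpass attenuates the stop band and passes the pass band", {
  fs <- 100
  n <- 3000
  t <- (0:(n - 1)) / fs
  mk <- function(x) sleepahi:::new_ecg_recording("r", "p", fs, x)
  rms <- function(v) sqrt(mean(v^2))

  slow <- sin(2 * pi * 0.3 * t)
  out <- bandpass_ecg(mk(slow))
  expect_lt(rms(out$samples), 0.05 * rms(slow))

  mid <- sin(2 * pi * 10 * t)
  out <- bandpass_ecg(mk(mid))
  core <- 500:2500  # ignore filter edge transients
  expect_lt(abs(rms(out$samples[core]) - rms(mid[core])) / rms(mid[core]),
            0.05)

  expect_identical(bandpass_ecg(mk(numeric(200)))$samples, numeric(200))
  expect_error(bandpass_ecg(mk(slow), 3, 60), "Nyquist")
  expect_error(bandpass_ecg(mk(slow), -1, 45), "low")
})

test_that("R-peak detection finds every beat of a clean 60-bpm train", {
  cfg <- sim_config(noise_sd = 0, wander_amp = 0, seed = 1)
  tach <- data.frame(time_s = 0:59, rr_s = 1, amp_mv = 1)
  ecg <- synthesize_ecg(tach, cfg, 60)
  prep <- bandpass_ecg(downsample_ecg(ecg))
  pk <- detect_r_peaks(prep)
  expect_gte(length(pk$times_s), 59)
  expect_lte(length(pk$times_s), 61)
  near <- sapply(tach$time_s, function(x) min(abs(pk$times_s - x)))
  expect_lt(max(near), 0.020)
})

test_that("a flat signal yields an empty peak train", {
  flat <- sleepahi:::new_ecg_recording("r", "p", 100, numeric(1000))
  pk <- detect_r_peaks(flat)
  expect_length(pk$times_s, 0)
})

test_that("detected RRI tracks a modulated tachogram almost exactly", {
  corpus <- make_corpus(1, 600, seed = 13)
  sim <- simulate_recording(corpus$cfg, 1)
  prep <- preprocess_recording(sim$ecg)
  dt <- prep$peaks$times_s
  tt <- sim$tachogram$time_s
  idx <- sapply(tt, function(x) which.min(abs(dt - x)))
  rr_true <- sim$tachogram$rr_s[-length(tt)]
  rr_det <- diff(dt[idx])
  expect_gt(cor(rr_true, rr_det), 0.99)
})

test_that("wander below 0.5 mV does not change the detected peak count", {
  cfg0 <- sim_config(noise_sd = 0, wander_amp = 0, seed = 4)
  set.seed(4)
  ev <- generate_event_schedule(300, cfg0, rate_per_h = 20)
  tach <- generate_rr_tachogram(300, ev, cfg0)
  clean <- synthesize_ecg(tach, cfg0, 300)
  n_clean <- length(detect_r_peaks(bandpass_ecg(downsample_ecg(clean)))$times_s)
  wander <- 0.5 * sin(2 * pi * 0.2 * (seq_along(clean$samples) - 1) / cfg0$fs)
  noisy <- sleepahi:::new_ecg_recording("r", "p", cfg0$fs,
                                        clean$samples + wander)
  n_wander <- length(detect_r_peaks(bandpass_ecg(downsample_ecg(noisy)))$times_s)
  expect_equal(n_clean, n_wander)
})

test_that("RRI/RPA derivation follows the later-peak timestamp convention", {
  pk <- structure(list(times_s = c(0, 1, 2, 3), amps_mv = c(1, 1.2, 0.9, 1)),
                  class = "peak_train")
  ser <- derive_rri_rpa(pk)
  expect_equal(ser$rri$value, c(1, 1, 1))
  expect_equal(ser$rri$time_s, c(1, 2, 3))
  expect_equal(ser$rpa$value, c(1, 1.2, 0.9, 1))
  expect_equal(ser$rpa$time_s, c(0, 1, 2, 3))

  pk2 <- structure(list(times_s = c(0, 0.8, 1.9), amps_mv = c(1, 1, 1)),
                   class = "peak_train")
  expect_equal(derive_rri_rpa(pk2)$rri$value, c(0.8, 1.1))

  pk1 <- structure(list(times_s = 1, amps_mv = 1), class = "peak_train")
  expect_error(derive_rri_rpa(pk1), "two")
})

test_that("fixed-length resampling is linear and edge-replicating", {
  const <- data.frame(time_s = c(0, 30, 60), value = 0.8)
  v <- resample_to_fixed(const, c(0, 60), 180)
  expect_length(v, 180)
  expect_true(all(v == 0.8))

  ramp <- data.frame(time_s = c(0, 60), value = c(0.8, 1.0))
  v <- resample_to_fixed(ramp, c(0, 60), 180)
  expect_equal(v[1], 0.8)
  expect_equal(v[180], 0.8 + 0.2 * 179 / 180, tolerance = 1e-12)
  expect_true(all(diff(v) > 0))
  expect_length(resample_to_fixed(ramp, c(0, 300), 900), 900)

  # exact on piecewise-linear input sampled at the knots
  knots <- data.frame(time_s = seq(0, 60, by = 5),
                      value = cumsum(runif(13, -1, 1)))
  grid <- 0 + (0:179) * 60 / 180
  expect_equal(resample_to_fixed(knots, c(0, 60), 180),
               approx(knots$time_s, knots$value, xout = grid)$y,
               tolerance = 1e-12)

  # beyond the observed range the nearest value is replicated
  v <- resample_to_fixed(ramp, c(-30, 30), 180)
  expect_true(all(v[1:89] == 0.8))

  expect_error(resample_to_fixed(data.frame(time_s = 1, value = 1),
                                 c(0, 60), 180), "insufficient")
})

test_that("window pairs have the contracted shapes at all grid positions", {
  corpus <- make_corpus(1, 400, seed = 5)
  prep <- preprocess_recording(corpus$recordings[[1]])
  for (t in c(0L, 5L, 20L)) {
    wp <- build_window_pair(prep, t)
    expect_equal(dim(wp$r1), c(2L, 180L))
    expect_equal(dim(wp$r5), c(2L, 900L))
    expect_true(all(is.finite(wp$r1)) && all(is.finite(wp$r5)))
    expect_false(wp$flag)
  }
  # constant-RR recording: constant RRI channel
  cfg0 <- sim_config(noise_sd = 0, wander_amp = 0, rr_jitter_sd = 0, seed = 1)
  ecg <- synthesize_ecg(data.frame(time_s = 0:119, rr_s = 1, amp_mv = 1),
                        cfg0, 120)
  prep0 <- preprocess_recording(ecg)
  wp <- build_window_pair(prep0, 6L)
  expect_lt(diff(range(wp$r1["rri", ])), 0.021)
})

test_that("a recording without detectable beats yields flagged fallbacks", {
  flat <- sleepahi:::new_ecg_recording("r", "p", 200, numeric(200 * 60))
  prep <- preprocess_recording(flat)
  expect_false(prep$ok)
  wp <- build_window_pair(prep, 2L)
  expect_true(wp$flag)
  expect_true(all(is.finite(wp$r1)))
})

test_that("simulate -> preprocess round trip recovers RR within 20 ms", {
  cfg <- sim_config(noise_sd = 0, wander_amp = 0, seed = 6)
  sim <- simulate_recording(cfg, 1)
  # only need a slice: rebuild a 5-minute recording for speed
  cfg5 <- sim_config(duration_s = 300, noise_sd = 0, wander_amp = 0,
                     seed = 6)
  sim <- simulate_recording(cfg5, 1)
  prep <- preprocess_recording(sim$ecg)
  dt <- prep$peaks$times_s
  tt <- sim$tachogram$time_s
  idx <- sapply(tt, function(x) which.min(abs(dt - x)))
  rr_true <- sim$tachogram$rr_s[-length(tt)]
  rr_det <- diff(dt[idx])
  expect_lt(mean(abs(rr_det - rr_true)), 0.020)
})

test_that("implausible RR intervals are replaced from the local window", {
  rri <- data.frame(time_s = seq(1, 60), value = rep(0.85, 60))
  rri$value[30] <- 2.6  # a missed beat would double the interval
  clean <- sleepahi:::clean_rri_series(rri)
  expect_equal(clean$value[30], 0.85)
  expect_equal(clean$value[-30], rri$value[-30])
})
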