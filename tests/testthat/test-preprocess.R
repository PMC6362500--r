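test_that("wavelet denoising is linear at zero and strips sub-0.5 Hz power", {
  z <- wavelet_denoise(ecg_signal(rep(0, 2048), 250))
  expect_equal(z$samples, rep(0, 2048))

  fs <- 250
  t <- seq(0, 60, by = 1 / fs)
  sine <- ecg_signal(sin(2 * pi * 0.2 * t), fs)
  den <- wavelet_denoise(sine)
  expect_length(den$samples, length(sine$samples))
  before <- band_power(sine$samples, fs, 0.15, 0.25)
  after <- band_power(den$samples, fs, 0.15, 0.25)
  expect_lt(after / before, 0.10) # >= 90% reduction at 0.2 Hz
})

test_that("denoising restores a drifted synthetic ECG to its clean template", {
  rr <- simulate_subject("mild", synthetic_config(duration = 10), seed = 5)$rr
  fs <- 128
  clean <- synthesize_ecg(rr, fs, drift_amp = 0, noise_sd = 0)
  dirty <- synthesize_ecg(rr, fs, drift_amp = 0.3, drift_freq = 0.3,
                          noise_sd = 0.02)
  den <- wavelet_denoise(dirty)
  expect_gte(cor(den$samples, clean$samples), 0.95)
})

test_that("denoising rejects signals shorter than the requested depth", {
  expect_error(wavelet_denoise(ecg_signal(rnorm(100), 250), max_level = 8),
               "maximum feasible level")
})

test_that("R-peak detection finds one peak per beat on synthetic ECG", {
  rr <- rr_series(rr_ms = rep(1000, 479)) # beats every 1.0 s, 480 s
  fs <- 250
  ecg <- synthesize_ecg(rr, fs)
  peaks <- detect_r_peaks(wavelet_denoise(ecg))
  expect_true(abs(length(peaks) - 480) <= 1)
  expect_true(all(diff(peaks) > 0))
})

test_that("flat signals yield an empty peak list with a warning", {
  expect_warning(p <- detect_r_peaks(ecg_signal(rep(0, 2500), 250)),
                 "flat")
  expect_length(p, 0)
})

test_that("refractory rule keeps a single peak from a close pair", {
  fs <- 250
  x <- numeric(1000)
  x[300] <- 1.0
  x[325] <- 0.9 # 0.1 s later
  p <- detect_r_peaks(ecg_signal(x, fs))
  expect_equal(p, 300L)
})

test_that("peak spacing never violates the refractory constraint", {
  for (seed in 1:5) {
    rr <- simulate_subject("severe", synthetic_config(duration = 10),
                           seed = seed)$rr
    ecg <- synthesize_ecg(rr, 128, noise_sd = 0.05, seed = seed)
    p <- detect_r_peaks(wavelet_denoise(ecg), refractory_s = 0.25)
    expect_true(all(diff(p) >= 0.25 * 128))
  }
})

test_that("rr_from_peaks converts sample indices to intervals", {
  rr <- rr_from_peaks(c(0, 250, 500), 250)
  expect_equal(rr$rr_ms, c(1000, 1000))
  expect_equal(rr_from_peaks(c(0, 200), 100)$rr_ms, 2000)
  expect_error(rr_from_peaks(c(5), 100), "at least 2")
  expect_error(rr_from_peaks(c(5, 5), 100), "increasing")
})

test_that("correct_rr replaces implausible intervals by the local median", {
  rr <- rr_series(rr_ms = c(800, 800, 3000, 800, 800))
  out <- correct_rr(rr, max_flag_frac = 0.5)
  expect_equal(out$rr_ms, rep(800, 5))
  expect_equal(out$quality_flags, c("ok", "ok", "corrected", "ok", "ok"))

  ok <- correct_rr(rr_series(rr_ms = c(800, 810, 790, 805)))
  expect_equal(ok$rr_ms, c(800, 810, 790, 805))
  expect_true(all(ok$quality_flags == "ok"))

  low <- correct_rr(rr_series(rr_ms = c(100, 800, 800)), max_flag_frac = 0.5)
  expect_equal(low$quality_flags[1], "corrected")
  expect_gte(low$rr_ms[1], 300)
})

test_that("correct_rr errors when too much of the record is artifact", {
  rr <- rr_series(rr_ms = c(rep(800, 6), rep(2500, 4)))
  expect_error(correct_rr(rr), "rejected")
})

test_that("correct_rr is idempotent", {
  sub <- simulate_subject("moderate",
                          synthetic_config(duration = 60, artifact_rate = 0.02),
                          seed = 9)
  once <- correct_rr(sub$rr)
  twice <- correct_rr(once)
  expect_equal(twice$rr_ms, once$rr_ms)
  expect_equal(twice$quality_flags == "corrected",
               once$quality_flags == "corrected")
})

test_that("synthesize -> denoise -> detect recovers RR within one sample", {
  cfg <- synthetic_config(duration = 10)
  for (seed in 1:2) {
    truth <- simulate_subject("mild", cfg, seed = seed)$rr
    for (fs in c(128, 250)) {
      den <- wavelet_denoise(synthesize_ecg(truth, fs, seed = seed))
      got <- rr_from_peaks(detect_r_peaks(den), fs)
      expect_equal(length(got$rr_ms), length(truth$rr_ms))
      expect_lte(max(abs(got$rr_ms - truth$rr_ms)), 1000 / fs)
    }
  }
})

test_that("the overnight window is cut by clock time when available", {
  rr <- rr_series(rr_ms = rep(1000, 4 * 3600)) # 4 h of beats
  expect_warning(w <- extract_sleep_window(rr, t0 = NULL, duration_min = 60),
                 "first")
  expect_equal(diff(range(w$beat_times)), 3600, tolerance = 1)
  # record starts at 21:00; window should begin 1 h in
  w2 <- extract_sleep_window(rr, t0 = 21 * 3600, duration_min = 60)
  expect_equal(length(w2$rr_ms), 3600, tolerance = 2)
})
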