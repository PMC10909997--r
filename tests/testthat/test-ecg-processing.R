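test_that("denoising a zero signal returns a zero signal", {
  rec <- ecg_record(numeric(2560), 256)
  out <- denoise(rec)
  expect_equal(out$samples, numeric(2560))
  expect_equal(out$fs, 256)
})

test_that("median-filter baseline removal attenuates slow wander by >= 20 dB", {
  rr <- suppressWarnings(gen_rr_series(
    autonomic_params(mean_rr = 900, jitter_sd = 0, seed = 1), 40))
  clean <- gen_ecg(rr, fs = 256, duration_s = 40)
  t <- (seq_along(clean$samples) - 1) / 256
  wander <- 300 * sin(2 * pi * 0.2 * t)
  rec <- ecg_record(clean$samples + wander, 256)
  out <- denoise(rec, median_window_ms = 600)
  before <- fft_band_power(rec$samples, 256, 0.15, 0.25)
  after <- fft_band_power(out$samples, 256, 0.15, 0.25)
  expect_gt(10 * log10(before / after), 20)
})

test_that("the 20-ms moving average attenuates a 50 Hz tone at 256 Hz", {
  rr <- suppressWarnings(gen_rr_series(
    autonomic_params(mean_rr = 900, jitter_sd = 0, seed = 2), 20))
  clean <- gen_ecg(rr, fs = 256, duration_s = 20)
  t <- (seq_along(clean$samples) - 1) / 256
  rec <- ecg_record(clean$samples + 40 * sin(2 * pi * 50 * t), 256)
  out <- denoise(rec, ma_window_ms = 20)
  before <- fft_band_power(rec$samples, 256, 49, 51)
  after <- fft_band_power(out$samples, 256, 49, 51)
  expect_lt(after, before / 10)
})

test_that("denoise rejects windows longer than the record", {
  rec <- ecg_record(rnorm(256), 256)
  expect_error(denoise(rec, median_window_ms = 5000), "longer than the record")
})

test_that("noise-free detection finds every beat within one sample", {
  rr <- suppressWarnings(gen_rr_series(
    autonomic_params(mean_rr = 1000, jitter_sd = 0, seed = 3), 60))
  ecg <- gen_ecg(rr, fs = 256)
  beats <- detect_qrs(denoise(ecg))
  expect_length(beats, length(ecg$annotations))
  expect_lte(max(abs(beats - ecg$annotations)) * 256, 1)
})

test_that("a flat-line record yields an empty beat list with a warning", {
  rec <- ecg_record(rep(3, 1024), 256)
  expect_warning(beats <- detect_qrs(rec), "flat-line")
  expect_length(beats, 0)
})

test_that("detection count is invariant to amplitude scaling", {
  rr <- suppressWarnings(gen_rr_series(autonomic_params(seed = 6), 45))
  ecg <- gen_ecg(rr, fs = 256)
  b1 <- detect_qrs(ecg)
  for (c in c(0.05, 20)) {
    scaled <- ecg_record(ecg$samples * c, 256)
    expect_equal(detect_qrs(scaled), b1)
  }
})

test_that("detection stays >= 99% sensitive and precise under 10 dB EMG noise", {
  rr <- gen_rr_series(autonomic_params(seed = 7), 120)
  clean <- gen_ecg(rr, fs = 256)
  emg_amp <- sd(clean$samples) / sqrt(10)
  noisy <- gen_ecg(rr, fs = 256, noise = noise_spec(emg_amp = emg_amp, seed = 8))
  beats <- detect_qrs(denoise(noisy))
  ann <- noisy$annotations
  tp <- sum(vapply(ann, function(a) any(abs(beats - a) <= 0.020), logical(1)))
  expect_gte(tp / length(ann), 0.99)
  expect_gte(tp / length(beats), 0.99)
})

test_that("extract_rr turns beat times into ms intervals and validates input", {
  expect_equal(extract_rr(c(0, 1, 2, 3))$intervals, c(1000, 1000, 1000))
  expect_equal(extract_rr(c(0, 0.8, 1.7))$intervals, c(800, 900))
  expect_error(extract_rr(c(0, 1, 0.5)), "strictly increasing")
  expect_error(extract_rr(2), "at least 2 beats")
})

test_that("a lone spike between equal neighbours is interpolated back", {
  iv <- c(rep(800, 10), 2000, rep(800, 10))
  rr <- rr_series(c(0, cumsum(iv) / 1000), iv)
  out <- clean_rr(rr, window = 11, n_mad = 3)
  expect_equal(out$intervals[11], 800)
  expect_identical(out$flags[11], "outlier_replaced")
  expect_equal(sum(out$flags == "outlier_replaced"), 1)
})

test_that("an outlier-free series passes through cleaning unchanged", {
  rr <- gen_rr_series(autonomic_params(jitter_sd = 5, seed = 10), 120)
  out <- clean_rr(rr)
  expect_equal(out$intervals, rr$intervals)
  expect_true(all(out$flags == "normal"))
})

test_that("cleaning is idempotent in both global and moving variants", {
  set.seed(11)
  rr0 <- gen_rr_series(autonomic_params(seed = 12), 200)
  iv <- rr0$intervals
  idx <- sample(length(iv), 5)
  iv[idx] <- iv[idx] * 2
  rr <- rr_series(rr0$beat_times, iv)
  for (g in c(TRUE, FALSE)) {
    once <- clean_rr(rr, global = g)
    twice <- clean_rr(once, global = g)
    expect_identical(twice$intervals, once$intervals)
    expect_identical(twice$flags, once$flags)
  }
})

test_that("physiological bounds flag intervals the MAD rule would keep", {
  iv <- c(rep(800, 30), 2300, rep(800, 30))
  rr <- rr_series(c(0, cumsum(iv) / 1000), iv)
  out <- clean_rr(rr, n_mad = 1e9)  # disarm the MAD rule
  expect_identical(out$flags[31], "outlier_replaced")
})

test_that("cleaning errors when everything is flagged", {
  rr <- rr_series(c(0, 3, 6, 9), c(3000, 3000, 3000))
  expect_error(clean_rr(rr), "every interval flagged")
})

test_that("end-to-end noise-free recovery: intervals within one sample period", {
  p <- autonomic_params(jitter_sd = 0, seed = 13)
  rr_true <- gen_rr_series(p, 120)
  ecg <- gen_ecg(rr_true, fs = 256)
  rr_est <- clean_rr(extract_rr(detect_qrs(denoise(ecg))))
  expect_equal(length(rr_est$intervals), length(rr_true$intervals))
  mae <- mean(abs(rr_est$intervals - rr_true$intervals))
  expect_lte(mae, 1000 / 256)
})
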