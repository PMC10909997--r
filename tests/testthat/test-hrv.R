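const_rr <- function(n = 61, ms = 1000) {
  rr_series(seq(0, by = ms / 1000, length.out = n + 1))
}

test_that("a constant series has HR 60 and zero variability", {
  td <- time_domain(const_rr())
  expect_equal(td$meanHR, 60)
  expect_equal(td$SDNN, 0)
  expect_identical(td$NN50, 0L)
  expect_equal(td$pNN50, 0)
  expect_equal(td$RMSSD, 0)
})

test_that("the four-interval worked example matches the definitions", {
  iv <- c(800, 860, 870, 800)
  rr <- rr_series(c(0, cumsum(iv) / 1000), iv)
  td <- time_domain(rr)
  expect_identical(td$NN50, 2L)  # diffs 60, 10, 70
  expect_equal(td$pNN50, 100 * 2 / 3, tolerance = 1e-12)
  expect_equal(td$RMSSD, sqrt((60^2 + 10^2 + 70^2) / 3), tolerance = 1e-12)
})

test_that("time-domain indices match the loop-based oracle on random series", {
  set.seed(21)
  for (i in 1:200) {
    iv <- runif(sample(10:200, 1), 500, 1500)
    rr <- rr_series(c(0, cumsum(iv) / 1000), iv)
    td <- time_domain(rr)
    o <- oracle_time_domain(iv)
    for (f in names(o)) {
      expect_equal(td[[f]], o[[f]], tolerance = 1e-9, label = f)
    }
  }
})

test_that("rescaling intervals scales SDNN/RMSSD and inverts meanHR", {
  rr <- gen_rr_series(autonomic_params(seed = 22), 120)
  td <- time_domain(rr)
  for (c in c(0.5, 2)) {
    rr_c <- rr_series(rr$beat_times[1] + c(0, cumsum(rr$intervals * c) / 1000),
                      rr$intervals * c)
    td_c <- time_domain(rr_c)
    expect_equal(td_c$SDNN, c * td$SDNN, tolerance = 1e-9)
    expect_equal(td_c$RMSSD, c * td$RMSSD, tolerance = 1e-9)
    expect_equal(td_c$meanHR, td$meanHR / c, tolerance = 1e-9)
  }
})

test_that("a constant tachogram yields a zero spectrum and NA ratios", {
  sp <- ar_spectrum(const_rr(100))
  expect_true(all(sp$density == 0))
  bp <- band_powers(sp)
  expect_equal(bp$aTotal, 0)
  expect_true(is.na(bp$LF_HF))
  expect_true(is.na(bp$nHF))
})

test_that("known HF modulation is recovered at the right peak frequency", {
  p <- autonomic_params(mean_rr = 850, a_lf = 0, a_hf = 0.05,
                        f_hf = 0.25, jitter_sd = 0, seed = 23)
  sp <- ar_spectrum(gen_rr_series(p, 300))
  expect_lt(abs(sp$frequencies[which.max(sp$density)] - 0.25), 0.02)
})

test_that("AR band powers agree with the Welch cross-check within 10%", {
  rr <- gen_rr_series(autonomic_params(seed = 24), 300)
  a <- band_powers(ar_spectrum(rr))
  w <- band_powers(welch_spectrum(rr))
  for (b in c("aLF", "aHF", "aTotal")) {
    expect_lt(abs(a[[b]] - w[[b]]) / w[[b]], 0.10, label = b)
  }
})

test_that("the AR spectrum integrates to the resampled series variance", {
  rr <- gen_rr_series(autonomic_params(seed = 25), 300)
  sp <- ar_spectrum(rr)
  total <- hrvload:::trapz(sp$frequencies, sp$density)
  xg <- hrvload:::resample_tachogram(rr, 4)
  expect_lt(abs(total - var(xg)) / var(xg), 0.10)
})

test_that("flat-spectrum band integrals match the band widths exactly", {
  f <- seq(0, 0.5, length.out = 4097)
  sp <- structure(list(frequencies = f, density = rep(1, length(f)),
                       ar_order = NA_integer_, resample_fs = 1,
                       method = "synthetic"), class = "hrv_spectrum")
  bp <- band_powers(sp)
  expect_equal(bp$aVLF, 0.037, tolerance = 1e-9)
  expect_equal(bp$aLF, 0.110, tolerance = 1e-9)
  expect_equal(bp$aHF, 0.250, tolerance = 1e-9)
  expect_equal(bp$aTotal, 0.397, tolerance = 1e-9)
  expect_equal(bp$nLF, 0.110 / 0.360, tolerance = 1e-9)
})

test_that("a spectrum with all mass in the HF band has nHF ~ 1", {
  f <- seq(0, 0.5, length.out = 4097)
  dens <- ifelse(f >= 0.15 & f <= 0.4, 1, 0)
  sp <- structure(list(frequencies = f, density = dens,
                       ar_order = NA_integer_, resample_fs = 1,
                       method = "synthetic"), class = "hrv_spectrum")
  bp <- band_powers(sp)
  expect_gt(bp$nHF, 0.999)
  expect_lt(bp$nLF, 0.001)
})

test_that("normalized powers and Total additivity hold on estimated spectra", {
  set.seed(26)
  for (i in 1:10) {
    rr <- gen_rr_series(autonomic_params(seed = 100 + i), 120)
    bp <- band_powers(ar_spectrum(rr))
    expect_equal(bp$nLF + bp$nHF, 1, tolerance = 1e-12)
    expect_equal(bp$aTotal, bp$aVLF + bp$aLF + bp$aHF, tolerance = 1e-12)
    expect_equal(bp$LF_HF, bp$aLF / bp$aHF, tolerance = 1e-12)
  }
})

test_that("symmetric LF/HF modulation gives an LF/HF ratio near unity", {
  p <- autonomic_params(a_lf = 0.04, a_hf = 0.04, seed = 27)
  feats <- hrv_features(gen_rr_series(p, 300))
  expect_gt(feats$LF_HF, 0.5)
  expect_lt(feats$LF_HF, 2)
})

test_that("halving the HF modulation strictly lowers estimated HF power", {
  base <- autonomic_params(a_hf = 0.06, seed = 28)
  halved <- autonomic_params(a_hf = 0.03, seed = 28)
  hf1 <- hrv_features(gen_rr_series(base, 300))$aHF
  hf2 <- hrv_features(gen_rr_series(halved, 300))$aHF
  expect_lt(hf2, hf1)
})

test_that("HF band power rises monotonically with the generator's a_hf", {
  levels <- c(0.01, 0.02, 0.03, 0.045, 0.06)
  med_hf <- sapply(seq_along(levels), function(i) {
    median(sapply(1:5, function(r) {
      p <- autonomic_params(a_hf = levels[i], seed = 300 + 10 * i + r)
      band_powers(ar_spectrum(gen_rr_series(p, 300)))$aHF
    }))
  })
  expect_gte(suppressWarnings(cor(seq_along(levels), med_hf, method = "spearman")), 0.9)
})

test_that("spectral preconditions are enforced", {
  expect_error(suppressWarnings(ar_spectrum(gen_rr_series(
    autonomic_params(seed = 29), 40))), "too short")
  rr <- gen_rr_series(autonomic_params(seed = 30), 65)
  expect_error(ar_spectrum(rr, ar_order = 1000), "order")
})
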