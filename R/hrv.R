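#' Time-domain HRV indices
#'
#' Computes the five classical time-domain indices from a cleaned NN series:
#' \itemize{
#'   \item meanHR: mean over intervals of the instantaneous rate
#'     60000/NN_i, beats/min (the alternative 60000/mean(NN) is available
#'     via `hr_method = "mean_rr"`; the two differ by Jensen's inequality);
#'   \item SDNN: sample standard deviation of the NN intervals, ms;
#'   \item NN50 / pNN50: count and percentage of successive differences
#'     strictly exceeding 50 ms (denominator = number of successive
#'     differences, n - 1);
#'   \item RMSSD: root mean square of successive differences, ms.
#' }
#'
#' @param rr an [rr_series] with >= 2 intervals.
#' @param hr_method `"instantaneous"` (default) or `"mean_rr"`.
#' @return A one-row tibble: meanHR, SDNN, NN50, pNN50, RMSSD.
#' @examples
#' time_domain(rr_series(c(0, 1, 2, 3)))
#' @export
time_domain <- function(rr, hr_method = c("instantaneous", "mean_rr")) {
  stopifnot(inherits(rr, "rr_series"))
  hr_method <- match.arg(hr_method)
  x <- rr$intervals
  stop_if(length(x) < 2L, "need at least 2 intervals")
  dx <- diff(x)
  tibble::tibble(
    meanHR = if (hr_method == "instantaneous") mean(60000 / x) else 60000 / mean(x),
    SDNN = sd(x),
    NN50 = sum(abs(dx) > 50),
    pNN50 = 100 * sum(abs(dx) > 50) / length(dx),
    RMSSD = sqrt(mean(dx^2)))
}

#' Autoregressive power spectrum of an RR tachogram
#'
#' The tachogram (NN interval value at each beat time) is mean-detrended,
#' cubic-spline interpolated onto an even grid at `resample_fs`, and an AR
#' model of order `ar_order` is fitted by the Burg method (forward/backward
#' prediction error minimization, stable on short windows). The one-sided
#' spectral density \eqn{P(f) = 2\sigma^2 / f_s / |1 - \sum_k a_k
#' e^{-2\pi i f k / f_s}|^2} is evaluated on a dense grid over
#' [0, resample_fs/2]; its integral matches the resampled series variance
#' (the AR power normalization). A zero-variance series yields a zero
#' spectrum.
#'
#' @param rr an [rr_series] spanning >= 60 s.
#' @param ar_order AR model order (default 16, common for 5-min windows).
#' @param resample_fs even-grid resampling rate, Hz (default 4).
#' @param n_freq number of frequency-grid points (default 2048).
#' @param aic if `TRUE`, select the order by AIC up to `ar_order`.
#' @return An object of class `hrv_spectrum`: `frequencies` (Hz), `density`
#'   (ms^2/Hz), `ar_order`, `resample_fs`, `method`.
#' @export
ar_spectrum <- function(rr, ar_order = 16L, resample_fs = 4, n_freq = 2048L,
                        aic = FALSE) {
  stopifnot(inherits(rr, "rr_series"))
  span <- diff(range(rr$beat_times))
  stop_if(span < 60, "series span (", round(span, 1),
          " s) too short for spectral analysis: need >= 60 s")
  xg <- resample_tachogram(rr, resample_fs)
  stop_if(ar_order >= length(xg) / 2,
          "AR fit: order must be below half the resampled length")
  f <- seq(0, resample_fs / 2, length.out = n_freq)
  if (var(xg) < 1e-12) {
    return(new_spectrum(f, rep(0, n_freq), ar_order, resample_fs, "ar_burg"))
  }
  fit <- tryCatch(
    ar.burg(xg, aic = aic, order.max = ar_order, demean = TRUE),
    error = function(e) stop("AR fit failed: ", conditionMessage(e), call. = FALSE))
  a <- fit$ar
  H <- rep(1 + 0i, n_freq)
  for (k in seq_along(a)) {
    H <- H - a[k] * exp(-2i * pi * f * k / resample_fs)
  }
  dens <- 2 * fit$var.pred / resample_fs / Mod(H)^2
  new_spectrum(f, dens, fit$order, resample_fs, "ar_burg")
}

# detrend + cubic-spline resample the tachogram to an even grid
resample_tachogram <- function(rr, resample_fs) {
  tt <- rr$beat_times[-1]
  xx <- rr$intervals
  sf <- stats::splinefun(tt, xx - mean(xx), method = "fmm")
  tg <- seq(tt[1], tt[length(tt)], by = 1 / resample_fs)
  sf(tg)
}

new_spectrum <- function(f, dens, ar_order, resample_fs, method) {
  stop_if(any(dens < 0), "spectral density must be nonnegative")
  structure(list(frequencies = f, density = dens, ar_order = ar_order,
                 resample_fs = resample_fs, method = method),
            class = "hrv_spectrum")
}

#' @export
print.hrv_spectrum <- function(x, ...) {
  cat(sprintf("<hrv_spectrum> %s, %d bins over [0, %g] Hz%s\n", x$method,
              length(x$frequencies), max(x$frequencies),
              if (is.na(x$ar_order)) "" else sprintf(", AR order %d", x$ar_order)))
  invisible(x)
}

#' Welch periodogram of an RR tachogram
#'
#' Nonparametric cross-check estimator for [ar_spectrum]: the same
#' detrend/resample step followed by Hann-windowed overlapped segment
#' averaging of the periodogram, normalized so the density integrates to the
#' resampled series variance.
#'
#' @inheritParams ar_spectrum
#' @param segment_s segment length in seconds (default 60: resolution 0.017 Hz, enough to separate the HRV bands, with ~9 averaged segments per 5-min window).
#' @param overlap fractional overlap between segments (default 0.5).
#' @return An `hrv_spectrum` with `method = "welch"`.
#' @export
welch_spectrum <- function(rr, resample_fs = 4, segment_s = 60, overlap = 0.5) {
  stopifnot(inherits(rr, "rr_series"))
  xg <- resample_tachogram(rr, resample_fs)
  nseg <- min(round(segment_s * resample_fs), length(xg))
  step <- max(1L, round(nseg * (1 - overlap)))
  starts <- seq(1L, length(xg) - nseg + 1L, by = step)
  win <- 0.5 - 0.5 * cos(2 * pi * seq_len(nseg) / (nseg + 1))
  U <- sum(win^2)
  acc <- numeric(nseg)
  for (s in starts) {
    seg <- xg[s:(s + nseg - 1L)]
    seg <- (seg - mean(seg)) * win
    acc <- acc + Mod(fft(seg))^2
  }
  pxx <- acc / length(starts) / (U * resample_fs)
  half <- seq_len(floor(nseg / 2) + 1L)
  f <- (half - 1L) / nseg * resample_fs
  dens <- pxx[half]
  dbl <- f > 0 & f < resample_fs / 2
  dens[dbl] <- 2 * dens[dbl]
  new_spectrum(f, dens, NA_integer_, resample_fs, "welch")
}

hrv_bands <- function() {
  list(VLF = c(0.003, 0.040), LF = c(0.040, 0.150), HF = c(0.150, 0.400))
}

#' Band powers and derived ratios from an HRV spectrum
#'
#' Integrates the spectral density (trapezoidal rule) over the standard HRV
#' bands — VLF 0.003-0.040 Hz, LF 0.040-0.150 Hz, HF 0.150-0.400 Hz — and
#' derives Total = VLF + LF + HF, the LF/HF ratio, and the normalized powers
#' nLF = LF/(LF+HF), nHF = HF/(LF+HF). Band edges are half-open
#' [low, high) except the closed final HF edge; with a continuous density
#' the trapezoidal integral is unaffected, and adjacent bands never double
#' count. Power below 0.003 Hz is excluded from Total. When HF is zero the
#' LF/HF ratio is reported as `NA` rather than infinity.
#'
#' @param spec an `hrv_spectrum` spanning at least [0, 0.4] Hz.
#' @return A one-row tibble: aVLF, aLF, aHF, aTotal (ms^2), LF_HF, nLF, nHF.
#' @export
band_powers <- function(spec) {
  stopifnot(inherits(spec, "hrv_spectrum"))
  f <- spec$frequencies
  stop_if(max(f) < 0.4, "spectrum grid must span at least [0, 0.4] Hz")
  one_band <- function(b) {
    lo <- b[1]; hi <- b[2]
    sel <- f > lo & f < hi
    fb <- c(lo, f[sel], hi)
    pb <- c(approx(f, spec$density, lo)$y, spec$density[sel],
            approx(f, spec$density, hi)$y)
    trapz(fb, pb)
  }
  p <- vapply(hrv_bands(), one_band, numeric(1))
  lfhf_sum <- p[["LF"]] + p[["HF"]]
  tibble::tibble(
    aVLF = p[["VLF"]], aLF = p[["LF"]], aHF = p[["HF"]],
    aTotal = sum(p),
    LF_HF = if (p[["HF"]] > 0) p[["LF"]] / p[["HF"]] else NA_real_,
    nLF = if (lfhf_sum > 0) p[["LF"]] / lfhf_sum else NA_real_,
    nHF = if (lfhf_sum > 0) p[["HF"]] / lfhf_sum else NA_real_)
}

#' Full HRV feature bundle for one recording window
#'
#' Composition of [time_domain], [ar_spectrum] and [band_powers]: one call
#' per recording window yields the complete 12-column feature set with the
#' standard column names (meanHR, SDNN, NN50, pNN50, RMSSD, aVLF, aLF, aHF,
#' aTotal, LF_HF, nLF, nHF).
#'
#' @inheritParams ar_spectrum
#' @inheritParams time_domain
#' @return A one-row tibble of the 12 features.
#' @examples
#' rr <- gen_rr_series(autonomic_params(seed = 5), 300)
#' hrv_features(rr)
#' @export
hrv_features <- function(rr, ar_order = 16L, resample_fs = 4,
                         hr_method = "instantaneous", aic = FALSE) {
  td <- time_domain(rr, hr_method = hr_method)
  fd <- band_powers(ar_spectrum(rr, ar_order = ar_order,
                                resample_fs = resample_fs, aic = aic))
  dplyr::bind_cols(td, fd)
}
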