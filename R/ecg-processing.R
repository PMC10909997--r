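#' Denoise an ECG record by median filtering and moving average
#'
#' Two-stage denoising: (1) a running-median baseline estimate over
#' `median_window_ms` is subtracted, removing baseline drift while leaving
#' QRS complexes intact (the window is wider than a QRS-T complex); (2) a
#' short centred moving average over `ma_window_ms` smooths powerline and
#' broadband myoelectric noise. Edges are handled by reflection; length and
#' sampling rate are preserved.
#'
#' @param record an [ecg_record].
#' @param median_window_ms baseline median window (default 600 ms).
#' @param ma_window_ms smoothing window (default 20 ms; ~5 samples at 256 Hz,
#'   which places a null of the averager near 50 Hz).
#' @return A denoised [ecg_record] (annotations carried over).
#' @export
denoise <- function(record, median_window_ms = 600, ma_window_ms = 20) {
  stopifnot(inherits(record, "ecg_record"))
  n <- length(record$samples)
  w_med <- round(median_window_ms / 1000 * record$fs)
  w_ma <- round(ma_window_ms / 1000 * record$fs)
  stop_if(w_med < 1 || w_ma < 1, "window shorter than one sample at fs")
  stop_if(w_med > n || w_ma > n, "window longer than the record")
  baseline <- moving_median(record$samples, w_med)
  x <- record$samples - baseline
  x <- moving_average(x, w_ma)
  ecg_record(x, record$fs, annotations = record$annotations,
             channel_label = record$channel_label)
}

#' Detect QRS complexes by the difference-threshold method
#'
#' The classic difference-based detector family: the signal is
#' differentiated, squared, and integrated over a moving window
#' (`integration_ms`), emphasizing the steep high-energy QRS slope. An
#' adaptive threshold tracks the running peak of the integrated signal with
#' exponential decay; within each supra-threshold region the beat is placed
#' at the argmax of the input signal, and no two beats may fall within the
#' refractory period. The threshold is relative, so detection is invariant
#' to amplitude scaling. A flat-line (zero-variance) record yields an empty
#' beat list with a warning rather than an error.
#'
#' @param record an [ecg_record], normally denoised first.
#' @param threshold_fraction fraction of the running peak used as threshold
#'   (default 0.4).
#' @param refractory_ms minimum beat-to-beat separation (default 250 ms).
#' @param integration_ms moving-window integration length (default 120 ms).
#' @param peak_halflife_s half-life of the running peak tracker's exponential
#'   decay (default 2 s).
#' @return Numeric vector of beat times in seconds.
#' @examples
#' rr <- gen_rr_series(autonomic_params(jitter_sd = 0, seed = 3), 60)
#' ecg <- gen_ecg(rr, fs = 256)
#' beats <- detect_qrs(ecg)
#' @export
detect_qrs <- function(record, threshold_fraction = 0.4, refractory_ms = 250,
                       integration_ms = 120, peak_halflife_s = 2) {
  stopifnot(inherits(record, "ecg_record"))
  x <- record$samples
  fs <- record$fs
  n <- length(x)
  stop_if(n / fs < 2, "record must be at least 2 s long")
  if (var(x) == 0) {
    warning("flat-line record: no beats detected", call. = FALSE)
    return(numeric(0))
  }
  d <- c(0, diff(x)) * fs
  sq <- d^2
  integ <- moving_average(sq, round(integration_ms / 1000 * fs))
  # running peak with exponential decay, primed on the first 2 s
  decay <- exp(log(0.5) / (peak_halflife_s * fs))
  peak <- numeric(n)
  p <- max(integ[seq_len(min(n, round(2 * fs)))])
  for (i in seq_len(n)) {
    p <- max(integ[i], p * decay)
    peak[i] <- p
  }
  above <- integ > threshold_fraction * peak
  if (!any(above)) return(numeric(0))
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  starts <- starts[r$values]; ends <- ends[r$values]
  cand_idx <- mapply(function(s, e) s - 1L + which.max(x[s:e]), starts, ends)
  cand_str <- integ[cand_idx]
  # refractory: greedy keep by descending integrated strength
  keep <- logical(length(cand_idx))
  refr <- refractory_ms / 1000 * fs
  for (j in order(cand_str, decreasing = TRUE)) {
    kept <- cand_idx[keep]
    if (!length(kept) || all(abs(kept - cand_idx[j]) >= refr)) keep[j] <- TRUE
  }
  sort(cand_idx[keep] - 1L) / fs
}

#' Extract RR intervals from detected beat times
#'
#' @param beat_times strictly increasing beat times, seconds (>= 2 beats).
#' @return An [rr_series] with intervals in ms, all flags `"normal"`.
#' @export
extract_rr <- function(beat_times) {
  stop_if(length(beat_times) < 2L, "need at least 2 beats")
  stop_if(any(diff(beat_times) <= 0), "beat times must be strictly increasing")
  rr_series(beat_times)
}

#' Screen and interpolate RR outliers (moving median + scaled MAD)
#'
#' Mirrors the standard moving-window fill-outliers rule: an interval is an
#' outlier when it deviates from the series median by more than `n_mad`
#' times the scaled MAD (consistency constant 1.4826) — the default rule of
#' the standard fill-outliers routine. A moving-window variant
#' (`global = FALSE`) uses the moving median and MAD of a `window`-beat
#' neighbourhood instead; note that with short windows the small-sample MAD
#' is noisy and flags a few percent of clean Gaussian data, which biases
#' short-term variability (RMSSD) downward after interpolation — hence the
#' global default. Intervals outside the physiological bounds are always
#' flagged. Outliers are replaced by linear interpolation between the
#' nearest non-outlier neighbours (nearest-value extension at the edges);
#' flags record the replacement. Output length equals input length; beat
#' times are not re-synthesized.
#'
#' @param rr an [rr_series] with >= 3 intervals.
#' @param window moving-window length in beats for the moving variant
#'   (odd; default 11).
#' @param n_mad outlier threshold in scaled-MAD units (default 3).
#' @param bounds physiological hard bounds on NN intervals, ms
#'   (default c(250, 2000)).
#' @param global use the series-wide median/MAD (default) rather than moving
#'   windows.
#' @return A cleaned [rr_series] with updated flags.
#' @export
clean_rr <- function(rr, window = 11L, n_mad = 3, bounds = c(250, 2000),
                     global = TRUE) {
  stopifnot(inherits(rr, "rr_series"))
  x <- rr$intervals
  n <- length(x)
  stop_if(n < 3L, "need at least 3 intervals to screen outliers")
  screen <- function(v) {
    if (global) {
      med <- rep(median(v), n)
      dev <- rep(mad(v), n)
    } else {
      w <- min(as.integer(window), if (n %% 2 == 1L) n else n - 1L)
      med <- moving_median(v, w)
      k <- (w - 1L) %/% 2L
      dev <- as.numeric(zoo::rollapply(reflect_pad(v, k), w, mad,
                                       align = "center"))
    }
    abs(v - med) > n_mad * dev | v < bounds[1] | v > bounds[2]
  }
  # iterate screen -> interpolate to a fixed point: outliers inflate the
  # first-pass scale estimate, so re-screening the repaired series can
  # expose points the contaminated threshold masked; at the fixed point
  # cleaning is idempotent.
  out <- rep(FALSE, n)
  xi <- x
  repeat {
    new_out <- screen(xi) & !out
    if (!any(new_out)) break
    out <- out | new_out
    stop_if(all(out), "every interval flagged as outlier: nothing to interpolate from")
    ok <- which(!out)
    xi <- x
    xi[out] <- approx(ok, x[ok], xout = which(out), rule = 2)$y
  }
  flags <- ifelse(out, "outlier_replaced", rr$flags)
  rr_series(rr$beat_times, xi, flags)
}
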