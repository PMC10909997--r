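#' Construct an ECG record
#'
#' @param samples voltage samples, microvolts.
#' @param fs sampling frequency, Hz.
#' @param annotations optional ground-truth beat times (s), strictly
#'   increasing and inside the record span.
#' @param channel_label free-text channel name.
#' @return An object of class `ecg_record`.
#' @export
ecg_record <- function(samples, fs, annotations = NULL, channel_label = "ECG") {
  samples <- as.numeric(samples)
  stop_if(fs <= 0, "fs must be positive")
  stop_if(any(!is.finite(samples)), "samples must be finite")
  if (!is.null(annotations) && length(annotations)) {
    stop_if(any(diff(annotations) <= 0), "annotations must be strictly increasing")
    stop_if(min(annotations) < 0 || max(annotations) > length(samples) / fs,
            "annotations must lie within the record span")
  }
  structure(list(samples = samples, fs = fs, annotations = annotations,
                 channel_label = channel_label),
            class = "ecg_record")
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("<ecg_record> %s: %d samples @ %g Hz (%.1f s)%s\n",
              x$channel_label, length(x$samples), x$fs, length(x$samples) / x$fs,
              if (is.null(x$annotations)) "" else
                sprintf(", %d annotated beats", length(x$annotations))))
  invisible(x)
}

#' Specify additive ECG noise components
#'
#' Three contaminants typical of ambulatory single-lead recordings: mains
#' (powerline) interference, broadband myoelectric (EMG) noise, and slow
#' baseline wander. An amplitude of 0 disables a component.
#'
#' @param powerline_hz mains frequency, Hz (default 50).
#' @param powerline_amp mains sine amplitude, uV.
#' @param emg_amp EMG noise standard deviation, uV (white noise band-limited
#'   to `emg_band`).
#' @param emg_band two-element passband for the EMG component, Hz.
#' @param baseline_hz baseline wander frequency, Hz (< 0.5).
#' @param baseline_amp baseline wander amplitude, uV.
#' @param seed integer seed for the stochastic components.
#' @return A list of class `noise_spec`.
#' @export
noise_spec <- function(powerline_hz = 50, powerline_amp = 0,
                       emg_amp = 0, emg_band = c(20, 120),
                       baseline_hz = 0.2, baseline_amp = 0, seed = NULL) {
  stop_if(powerline_amp < 0 || emg_amp < 0 || baseline_amp < 0,
          "noise amplitudes must be >= 0")
  stop_if(baseline_hz >= 0.5, "baseline wander must be slower than 0.5 Hz")
  structure(list(powerline_hz = powerline_hz, powerline_amp = powerline_amp,
                 emg_amp = emg_amp, emg_band = emg_band,
                 baseline_hz = baseline_hz, baseline_amp = baseline_amp,
                 seed = seed),
            class = "noise_spec")
}

# QRS-like template: dominant R deflection flanked by small Q and S dips,
# total width ~90 ms. Returns voltage samples centred on the R peak.
qrs_template <- function(fs, width_ms = 90, r_amp = 1000) {
  half <- round(width_ms / 2 / 1000 * fs)
  t <- (-half:half) / fs * 1000            # ms relative to R peak
  r <- r_amp * exp(-(t / 14)^2)
  q <- -0.12 * r_amp * exp(-((t + 28) / 9)^2)
  s <- -0.20 * r_amp * exp(-((t - 28) / 9)^2)
  r + q + s
}

#' Synthesize a single-lead ECG from an RR series
#'
#' Places one QRS-like template (dominant R wave, width about 90 ms) at each
#' beat time, then adds the noise components of `noise`: a powerline sine,
#' band-limited broadband EMG noise, and slow sinusoidal baseline wander.
#' Ground-truth beat times are stored as annotations on the record.
#'
#' @param rr an [rr_series], or `NULL` for an empty (zero-signal) record.
#' @param fs sampling frequency, Hz (>= 128; study hardware used 256).
#' @param noise a [noise_spec]; defaults to noise-free.
#' @param duration_s record length; defaults to span of `rr` plus 1 s.
#' @param r_amp R-wave amplitude, uV.
#' @return An [ecg_record] with annotations.
#' @examples
#' rr <- gen_rr_series(autonomic_params(jitter_sd = 0, seed = 1), 60)
#' ecg <- gen_ecg(rr, fs = 256)
#' @export
gen_ecg <- function(rr, fs = 256, noise = noise_spec(), duration_s = NULL,
                    r_amp = 1000) {
  stop_if(fs < 128, "fs must be >= 128 Hz")
  if (is.null(rr)) {
    stop_if(is.null(duration_s), "duration_s required for an empty record")
    n <- round(duration_s * fs)
    x <- numeric(n)
    beats <- numeric(0)
  } else {
    stopifnot(inherits(rr, "rr_series"))
    beats <- rr$beat_times
    tmpl <- qrs_template(fs, r_amp = r_amp)
    width_s <- length(tmpl) / fs
    stop_if(min(rr$intervals) / 1000 < width_s,
            "beat interval shorter than the QRS template width (",
            round(width_s * 1000), " ms): physiologically impossible input")
    if (is.null(duration_s)) duration_s <- max(beats) + 1
    n <- round(duration_s * fs)
    x <- numeric(n)
    half <- (length(tmpl) - 1L) %/% 2L
    for (b in beats) {
      c0 <- round(b * fs) + 1L
      lo <- c0 - half; hi <- c0 + half
      sl <- max(lo, 1L):min(hi, n)
      if (length(sl)) x[sl] <- x[sl] + tmpl[sl - lo + 1L]
    }
  }
  tt <- (seq_len(n) - 1L) / fs
  with_seed(noise$seed, {
    if (noise$powerline_amp > 0) {
      x <- x + noise$powerline_amp * sin(2 * pi * noise$powerline_hz * tt + runif(1, 0, 2 * pi))
    }
    if (noise$baseline_amp > 0) {
      x <- x + noise$baseline_amp * sin(2 * pi * noise$baseline_hz * tt + runif(1, 0, 2 * pi))
    }
    if (noise$emg_amp > 0) {
      w <- rnorm(n)
      hi <- min(noise$emg_band[2], 0.45 * fs)
      bf <- signal::butter(4, c(noise$emg_band[1], hi) / (fs / 2), type = "pass")
      e <- signal::filtfilt(bf, w)
      x <- x + noise$emg_amp * e / sd(e)
    }
  })
  ecg_record(x, fs, annotations = if (length(beats)) beats else NULL)
}
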