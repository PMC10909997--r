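#' Construct an RR interval series
#'
#' The package's core container: ordered beat times (s) with the
#' normal-to-normal intervals between them (ms) and a per-interval quality
#' flag (`"normal"` or `"outlier_replaced"`).
#'
#' @param beat_times strictly increasing beat times in seconds.
#' @param intervals optional intervals in ms; defaults to successive
#'   differences of `beat_times` * 1000. Length must be
#'   `length(beat_times) - 1`.
#' @param flags per-interval character flags; default all `"normal"`.
#' @return An object of class `rr_series`.
#' @export
rr_series <- function(beat_times, intervals = NULL, flags = NULL) {
  beat_times <- as.numeric(beat_times)
  stop_if(length(beat_times) < 2L, "an rr_series needs at least 2 beats")
  stop_if(any(!is.finite(beat_times)), "beat times must be finite")
  stop_if(any(diff(beat_times) <= 0), "beat times must be strictly increasing")
  if (is.null(intervals)) intervals <- diff(beat_times) * 1000
  intervals <- as.numeric(intervals)
  stop_if(length(intervals) != length(beat_times) - 1L,
          "need one interval per successive beat pair")
  stop_if(any(intervals <= 0), "all intervals must be positive")
  if (is.null(flags)) flags <- rep("normal", length(intervals))
  stop_if(!all(flags %in% c("normal", "outlier_replaced")),
          "flags must be 'normal' or 'outlier_replaced'")
  structure(list(beat_times = beat_times, intervals = intervals,
                 flags = as.character(flags)),
            class = "rr_series")
}

#' @export
print.rr_series <- function(x, ...) {
  cat(sprintf("<rr_series> %d intervals over %.1f s; mean RR %.1f ms; %d replaced\n",
              length(x$intervals), diff(range(x$beat_times)),
              mean(x$intervals), sum(x$flags == "outlier_replaced")))
  invisible(x)
}

#' @export
length.rr_series <- function(x) length(x$intervals)

#' Parameters of the autonomic RR generator
#'
#' Bundles the integral pulse frequency modulation (IPFM) parameters: mean RR
#' interval, the low- and high-frequency modulation amplitudes (dimensionless
#' fractions of the mean rate), their centre frequencies, and white
#' beat-to-beat jitter. The LF/HF frequency constraints mirror the standard
#' HRV band definitions (LF 0.040-0.150 Hz, HF 0.150-0.400 Hz).
#'
#' @param mean_rr mean RR interval, ms (> 0).
#' @param a_lf,a_hf modulation amplitudes; `a_lf + a_hf` must be < 1 so the
#'   instantaneous rate stays positive.
#' @param f_lf,f_hf modulation frequencies in Hz, constrained to their bands.
#' @param jitter_sd white beat-to-beat noise sd, ms.
#' @param seed integer seed for phases and jitter.
#' @return A validated list of class `autonomic_params`.
#' @export
autonomic_params <- function(mean_rr = 850, a_lf = 0.04, a_hf = 0.04,
                             f_lf = 0.1, f_hf = 0.25, jitter_sd = 20,
                             seed = NULL) {
  stop_if(mean_rr <= 0, "mean_rr must be positive")
  stop_if(a_lf < 0 || a_hf < 0 || a_lf + a_hf >= 1,
          "need 0 <= a_lf + a_hf < 1")
  stop_if(f_lf < 0.040 || f_lf >= 0.150, "f_lf must lie in [0.040, 0.150) Hz")
  stop_if(f_hf < 0.150 || f_hf >= 0.400, "f_hf must lie in [0.150, 0.400) Hz")
  stop_if(jitter_sd < 0, "jitter_sd must be >= 0")
  structure(list(mean_rr = mean_rr, a_lf = a_lf, a_hf = a_hf,
                 f_lf = f_lf, f_hf = f_hf, jitter_sd = jitter_sd, seed = seed),
            class = "autonomic_params")
}

#' Generate an RR series by integral pulse frequency modulation
#'
#' Emits a beat each time the integral of the modulated instantaneous rate
#' \deqn{m(t) = \frac{1}{\bar{RR}}\left[1 + a_{LF}\sin(2\pi f_{LF} t + \phi_1)
#'   + a_{HF}\sin(2\pi f_{HF} t + \phi_2)\right]}
#' crosses a successive integer. Phases are drawn from the seeded stream;
#' white jitter of sd `jitter_sd` ms is then added per interval. This is the
#' standard test-bench model for HRV spectral estimators: the LF and HF
#' modulation amplitudes map directly onto LF and HF band power.
#'
#' @param params an [autonomic_params] object.
#' @param duration_s recording length in seconds; below 60 s a warning is
#'   issued because the series is too short for spectral analysis.
#' @return An [rr_series].
#' @examples
#' rr <- gen_rr_series(autonomic_params(seed = 1), duration_s = 120)
#' @export
gen_rr_series <- function(params, duration_s) {
  stopifnot(inherits(params, "autonomic_params"))
  if (duration_s < 60) {
    warning("duration < 60 s: too short for spectral analysis", call. = FALSE)
  }
  with_seed(params$seed, {
    T0 <- params$mean_rr / 1000
    modulated <- params$a_lf > 0 || params$a_hf > 0
    phi1 <- if (modulated) runif(1, 0, 2 * pi) else 0
    phi2 <- if (modulated) runif(1, 0, 2 * pi) else 0
    # analytic integral of the modulated rate
    M <- function(t) {
      out <- t / T0
      if (params$a_lf > 0) {
        out <- out + params$a_lf / (2 * pi * params$f_lf * T0) *
          (cos(phi1) - cos(2 * pi * params$f_lf * t + phi1))
      }
      if (params$a_hf > 0) {
        out <- out + params$a_hf / (2 * pi * params$f_hf * T0) *
          (cos(phi2) - cos(2 * pi * params$f_hf * t + phi2))
      }
      out
    }
    tg <- seq(0, duration_s, by = min(T0, 0.25) / 50)
    Mg <- M(tg)
    k <- seq(0, floor(Mg[length(Mg)]))
    beats <- approx(Mg, tg, xout = k, ties = "ordered")$y
    stop_if(length(beats) < 2L, "duration too short to emit two beats")
    iv <- diff(beats) * 1000
    if (params$jitter_sd > 0) {
      iv <- iv + rnorm(length(iv), 0, params$jitter_sd)
      iv <- pmax(iv, 200)  # physiologically floor against extreme jitter draws
      beats <- beats[1] + c(0, cumsum(iv) / 1000)
    }
    rr_series(beats, iv)
  })
}
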