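#' Study conditions: cognitive load x physical load
#'
#' The design crosses three cognitive-load levels (1-, 2-, 3-back) with three
#' physical-load levels (none, medium, high dumbbell resistance), giving nine
#' within-subject conditions.
#'
#' @return A tibble with columns `cl` (integer 1:3) and `pl`
#'   (factor none/medium/high), nine rows.
#' @export
condition_grid <- function() {
  tidyr::expand_grid(cl = 1:3, pl = pl_levels())
}

#' @rdname condition_grid
#' @export
pl_levels <- function() factor(c("none", "medium", "high"),
                               levels = c("none", "medium", "high"))

#' Condition effect map for the synthetic study
#'
#' One row per (cl, pl) condition giving multipliers on the autonomic
#' generator (mean RR, LF/HF modulation amplitude) and additive shifts on the
#' behavioral and subjective generators. The default map encodes the
#' directions the dual-task literature reports: rising physical load lowers
#' the mean RR interval (raises heart rate) and suppresses HF (vagal)
#' modulation; rising cognitive load lengthens reaction times, raises the
#' miss rate, and raises subjective workload. At medium physical load the
#' defaults are an HF-amplitude multiplier of 0.7 and a mean-RR multiplier of
#' 0.92 (an 8% drop).
#'
#' @param rr_mult,a_lf_mult,a_hf_mult named numeric vectors over physical-load
#'   levels (multipliers, > 0).
#' @param rt_shift_cl,miss_shift_cl,tlx_shift_cl,rt_scale_shift_cl additive
#'   effects of cognitive level (length 3, levels 1:3).
#' @param rt_shift_pl,miss_shift_pl,tlx_shift_pl additive effects of physical
#'   level (named over none/medium/high).
#' @return A tibble of class `effect_map`, nine rows.
#' @examples
#' default_effect_map()
#' identity_effect_map()
#' @export
default_effect_map <- function(
    rr_mult   = c(none = 1, medium = 0.92, high = 0.85),
    a_lf_mult = c(none = 1, medium = 1.00, high = 1.00),
    a_hf_mult = c(none = 1, medium = 0.70, high = 0.50),
    rt_shift_cl = c(0, 80, 160), rt_shift_pl = c(none = 0, medium = 20, high = 40),
    rt_scale_shift_cl = c(0, 0.04, 0.08),
    miss_shift_cl = c(0, 0.07, 0.15), miss_shift_pl = c(none = 0, medium = 0.02, high = 0.04),
    tlx_shift_cl = c(0, 3, 6), tlx_shift_pl = c(none = 0, medium = 1.5, high = 3)) {
  stop_if(any(c(rr_mult, a_lf_mult, a_hf_mult) <= 0), "multipliers must be > 0")
  g <- condition_grid()
  pl <- as.character(g$pl)
  out <- tibble::tibble(
    cl = g$cl, pl = g$pl,
    rr_mult = unname(rr_mult[pl]),
    a_lf_mult = unname(a_lf_mult[pl]),
    a_hf_mult = unname(a_hf_mult[pl]),
    rt_shift_ms = rt_shift_cl[g$cl] + unname(rt_shift_pl[pl]),
    rt_scale_shift = rt_scale_shift_cl[g$cl],
    miss_shift = miss_shift_cl[g$cl] + unname(miss_shift_pl[pl]),
    fa_shift = 0.01 * (g$cl - 1),
    tlx_shift = tlx_shift_cl[g$cl] + unname(tlx_shift_pl[pl]))
  class(out) <- c("effect_map", class(out))
  out
}

#' @rdname default_effect_map
#' @export
identity_effect_map <- function() {
  default_effect_map(
    rr_mult = c(none = 1, medium = 1, high = 1),
    a_hf_mult = c(none = 1, medium = 1, high = 1),
    rt_shift_cl = c(0, 0, 0), rt_shift_pl = c(none = 0, medium = 0, high = 0),
    rt_scale_shift_cl = c(0, 0, 0),
    miss_shift_cl = c(0, 0, 0), miss_shift_pl = c(none = 0, medium = 0, high = 0),
    tlx_shift_cl = c(0, 0, 0), tlx_shift_pl = c(none = 0, medium = 0, high = 0)) |>
    dplyr::mutate(fa_shift = 0)
}

effect_row <- function(effects, cl, pl) {
  r <- effects[effects$cl == cl & as.character(effects$pl) == as.character(pl), ]
  stop_if(nrow(r) != 1L, "condition (", cl, ", ", pl, ") not found in effect map")
  r
}

#' Simulate a behavioral response log for one n-back trial
#'
#' For each target stimulus a hit occurs with probability
#' `1 - miss_prob`; hit reaction times are drawn from a lognormal whose
#' location is shifted by the condition's effect-map entry. Non-target
#' stimuli draw false alarms with a small condition-dependent probability.
#' Responses are confined to the response window (target onset to next
#' stimulus onset).
#'
#' @param trial an `nback_trial`.
#' @param cl,pl the condition (cognitive level 1:3, physical level
#'   none/medium/high).
#' @param effects an effect map (see [default_effect_map]).
#' @param seed integer seed.
#' @param rt_location_ms,rt_sdlog baseline lognormal median RT (ms) and log-sd.
#' @param miss_prob,false_alarm_prob baseline probabilities.
#' @param rt_offset_ms subject-level additive RT offset (random effect).
#' @return A tibble of class `response_log`: one row per stimulus with
#'   `onset`, `is_target`, `responded`, `rt` (ms, `NA` when no response),
#'   plus a `response_window_ms` attribute.
#' @export
gen_response_log <- function(trial, cl = 1, pl = "none",
                             effects = default_effect_map(), seed = NULL,
                             rt_location_ms = 550, rt_sdlog = 0.18,
                             miss_prob = 0.04, false_alarm_prob = 0.02,
                             rt_offset_ms = 0) {
  stopifnot(inherits(trial, "nback_trial"))
  ef <- effect_row(effects, cl, pl)
  window_ms <- (trial$stimulus_duration + trial$inter_stimulus_interval) * 1000
  loc <- rt_location_ms + ef$rt_shift_ms + rt_offset_ms
  sdl <- max(rt_sdlog + ef$rt_scale_shift, 0)
  pmiss <- min(max(miss_prob + ef$miss_shift, 0), 1)
  pfa <- min(max(false_alarm_prob + ef$fa_shift, 0), 1)
  n <- length(trial$letters)
  with_seed(seed, {
    responded <- logical(n)
    rt <- rep(NA_real_, n)
    for (i in seq_len(n)) {
      if (trial$target_flags[i]) {
        if (runif(1) >= pmiss) {
          responded[i] <- TRUE
          rt[i] <- min(rlnorm(1, log(loc), sdl), window_ms)
        }
      } else if (runif(1) < pfa) {
        responded[i] <- TRUE
        rt[i] <- min(rlnorm(1, log(loc), max(sdl, 0.05)), window_ms)
      }
    }
    out <- tibble::tibble(onset = trial$stimulus_onsets,
                          is_target = trial$target_flags,
                          responded = responded, rt = rt)
    attr(out, "response_window_ms") <- window_ms
    class(out) <- c("response_log", class(out))
    out
  })
}

tlx_dimensions <- function() {
  c("mental", "physical", "temporal", "performance", "effort", "frustration")
}

#' Simulate a NASA-TLX response for one condition
#'
#' Six ratings on the 21-point scale (stored 0-20) are drawn around
#' condition-shifted dimension means and clipped to scale; the 15 pairwise
#' importance choices pick, for every unordered dimension pair, the dimension
#' with the larger underlying (pre-clipping) demand, ties broken by the
#' seeded stream.
#'
#' @param cl,pl the condition.
#' @param effects an effect map.
#' @param seed integer seed.
#' @param base_means named baseline means per dimension (0-20 scale).
#' @param rating_sd rating noise sd; 0 gives deterministic ratings.
#' @return A `tlx_response` (see [tlx_response]).
#' @export
gen_tlx_response <- function(cl = 1, pl = "none", effects = default_effect_map(),
                             seed = NULL,
                             base_means = c(mental = 8, physical = 4, temporal = 7,
                                            performance = 7, effort = 8, frustration = 5),
                             rating_sd = 2.5) {
  ef <- effect_row(effects, cl, pl)
  stop_if(!identical(sort(names(base_means)), sort(tlx_dimensions())),
          "base_means must be named over the six TLX dimensions")
  mu <- base_means[tlx_dimensions()] + ef$tlx_shift
  with_seed(seed, {
    latent <- mu + if (rating_sd > 0) rnorm(6, 0, rating_sd) else 0
    ratings <- pmin(pmax(round(latent), 0), 20)
    names(ratings) <- tlx_dimensions()
    pairs <- utils::combn(tlx_dimensions(), 2)
    choice <- character(ncol(pairs))
    for (j in seq_len(ncol(pairs))) {
      a <- pairs[1, j]; b <- pairs[2, j]
      choice[j] <- if (latent[a] > latent[b]) a
                   else if (latent[b] > latent[a]) b
                   else sample(c(a, b), 1)
    }
    tlx_response(ratings,
                 tibble::tibble(dim_a = pairs[1, ], dim_b = pairs[2, ],
                                choice = choice))
  })
}
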