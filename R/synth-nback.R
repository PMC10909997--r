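#' Generate an n-back letter sequence with an exact target count
#'
#' Builds one trial of the n-back working-memory task: an ordered letter
#' sequence in which exactly `n_targets` positions repeat the letter shown
#' `n_back` positions earlier, and no other position does. Stimulus onsets
#' follow the configured cadence (each letter shown for
#' `stimulus_duration` s followed by `inter_stimulus_interval` s blank).
#'
#' @param n_back integer >= 1; the lag defining a target.
#' @param n_letters trial length (default 20 letters).
#' @param n_targets exact number of target positions (default 5).
#' @param alphabet character vector of at least 2 distinct symbols; defaults
#'   to 8 consonants to avoid vowel chunking strategies.
#' @param seed integer seed; identical seeds give identical trials.
#' @param stimulus_duration seconds each letter is displayed (default 0.5).
#' @param inter_stimulus_interval blank seconds between letters (default 1.5).
#' @return An object of class `nback_trial` with fields `n_back`, `letters`,
#'   `target_flags`, `stimulus_onsets` (s from stimulus phase start),
#'   `stimulus_duration`, `inter_stimulus_interval`.
#' @examples
#' tr <- gen_nback_sequence(2, seed = 1)
#' sum(tr$target_flags)
#' @export
gen_nback_sequence <- function(n_back, n_letters = 20L, n_targets = 5L,
                               alphabet = c("B", "D", "F", "G", "K", "P", "S", "T"),
                               seed = NULL,
                               stimulus_duration = 0.5,
                               inter_stimulus_interval = 1.5) {
  n_back <- as.integer(n_back)
  n_letters <- as.integer(n_letters)
  n_targets <- as.integer(n_targets)
  stop_if(n_back < 1L, "n_back must be >= 1")
  stop_if(length(unique(alphabet)) < 2L, "alphabet must contain at least 2 distinct symbols")
  stop_if(n_targets < 0L, "n_targets must be >= 0")
  stop_if(n_targets > n_letters - n_back,
          "infeasible: n_targets (", n_targets, ") exceeds n_letters - n_back (",
          n_letters - n_back, ")")
  with_seed(seed, {
    eligible <- seq.int(n_back + 1L, length.out = n_letters - n_back)
    target_pos <- sort(sample(eligible, n_targets))
    flags <- rep(FALSE, n_letters)
    flags[target_pos] <- TRUE
    letters_out <- character(n_letters)
    for (i in seq_len(n_letters)) {
      if (flags[i]) {
        letters_out[i] <- letters_out[i - n_back]
      } else {
        pool <- alphabet
        if (i > n_back) pool <- setdiff(pool, letters_out[i - n_back])
        letters_out[i] <- sample(pool, 1L)
      }
    }
    onsets <- (seq_len(n_letters) - 1L) * (stimulus_duration + inter_stimulus_interval)
    structure(
      list(n_back = n_back, letters = letters_out, target_flags = flags,
           stimulus_onsets = onsets, stimulus_duration = stimulus_duration,
           inter_stimulus_interval = inter_stimulus_interval),
      class = "nback_trial")
  })
}

#' @export
print.nback_trial <- function(x, ...) {
  cat(sprintf("<nback_trial> %d-back, %d letters, %d targets\n",
              x$n_back, length(x$letters), sum(x$target_flags)))
  cat(" ", paste(ifelse(x$target_flags, tolower(x$letters), x$letters),
                 collapse = " "), "\n")
  invisible(x)
}

#' Assemble a run schedule of consecutive n-back trials
#'
#' A run of a given n-back type is `n_trials` consecutive trials, each
#' occupying `per_trial_duration` seconds (instruction + 20 stimuli at a 2-s
#' cadence + inter-trial break). The default 6 x 50 s run lasts 5 minutes.
#'
#' @param trial an `nback_trial` (or list of them, recycled to `n_trials`).
#' @param n_trials number of consecutive trials in the run (default 6).
#' @param per_trial_duration seconds per trial including instruction and break
#'   (default 50).
#' @param instruction_duration seconds of instruction before the letters
#'   (default 2).
#' @return An object of class `nback_run` with `trials`, `trial_onsets` (s),
#'   `per_trial_duration`, `instruction_duration`, `inter_trial_break`,
#'   `total_duration`.
#' @export
build_run_schedule <- function(trial, n_trials = 6L, per_trial_duration = 50,
                               instruction_duration = 2) {
  trials <- if (inherits(trial, "nback_trial")) rep(list(trial), n_trials) else trial
  stop_if(length(trials) != n_trials, "need one trial spec per trial")
  n_trials <- as.integer(n_trials)
  stop_if(n_trials < 1L, "n_trials must be >= 1")
  span <- function(tr) {
    instruction_duration + max(tr$stimulus_onsets) +
      tr$stimulus_duration + tr$inter_stimulus_interval
  }
  active <- vapply(trials, span, numeric(1))
  stop_if(per_trial_duration < max(active),
          "per_trial_duration (", per_trial_duration,
          " s) is shorter than the active stimulus span (", max(active), " s)")
  onsets <- (seq_len(n_trials) - 1L) * per_trial_duration
  structure(
    list(trials = trials, trial_onsets = onsets,
         per_trial_duration = per_trial_duration,
         instruction_duration = instruction_duration,
         inter_trial_break = per_trial_duration - max(active),
         total_duration = n_trials * per_trial_duration),
    class = "nback_run")
}

#' @export
print.nback_run <- function(x, ...) {
  cat(sprintf("<nback_run> %d trials x %g s = %g s total\n",
              length(x$trials), x$per_trial_duration, x$total_duration))
  invisible(x)
}
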