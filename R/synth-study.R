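#' Generate a complete synthetic dual-task study dataset
#'
#' Emulates the full within-subject design: each subject completes all nine
#' (cognitive x physical) load conditions. Per subject x condition the
#' generator produces a 5-minute RR series (optionally with the synthetic
#' ECG), one behavioral response log per trial of the run, and one NASA-TLX
#' response. Subject-level random effects (a normal perturbation of the
#' baseline mean RR and of the RT location) are shared across that subject's
#' conditions. Task-order labels follow the three-subgroup rotation used to
#' counterbalance n-back order (group 1: 1-2-3, group 2: 2-3-1, group 3:
#' 3-1-2), with subjects allocated to subgroups as evenly as possible
#' (sizes differ by at most 1).
#'
#' @param n_subjects number of subjects (>= 2; the study used 35).
#' @param effects condition effect map (default [default_effect_map]).
#' @param seed master seed; every subject/condition stream is derived from
#'   it, so the full dataset is reproducible.
#' @param duration_s RR recording length per condition (default 300 s: a
#'   6 x 50 s run).
#' @param base_params baseline [autonomic_params] before subject and
#'   condition effects.
#' @param n_trials trials per run (default 6).
#' @param subject_rr_sd,subject_rt_sd sd of the subject random effects on
#'   mean RR and RT location, ms (defaults 50 and 50).
#' @param include_ecg also synthesize the noisy ECG per condition (slower;
#'   default `FALSE`).
#' @param ecg_noise [noise_spec] used when `include_ecg = TRUE`.
#' @return A list of class `study_dataset`: `subjects` (tibble: subject,
#'   subgroup, task_order), `records` (tibble: subject, cl, pl, rr, logs,
#'   tlx, and optionally ecg, as list-columns), `effects`, `seed`.
#' @examples
#' ds <- gen_study_dataset(3, seed = 1, duration_s = 90)
#' ds$subjects
#' @export
gen_study_dataset <- function(n_subjects = 35L, effects = default_effect_map(),
                              seed = 1L, duration_s = 300,
                              base_params = autonomic_params(),
                              n_trials = 6L,
                              subject_rr_sd = 50, subject_rt_sd = 50,
                              include_ecg = FALSE, ecg_noise = noise_spec()) {
  n_subjects <- as.integer(n_subjects)
  stop_if(n_subjects < 2L, "need at least 2 subjects")
  orders <- list(c(1, 2, 3), c(2, 3, 1), c(3, 1, 2))
  subjects <- with_seed(child_seed(seed, "alloc"), {
    subgroup <- sample(rep_len(1:3, n_subjects))
    tibble::tibble(
      subject = sprintf("S%02d", seq_len(n_subjects)),
      subgroup = subgroup,
      task_order = vapply(subgroup, function(g) paste(orders[[g]], collapse = "-"),
                          character(1)),
      rr_offset_ms = rnorm(n_subjects, 0, subject_rr_sd),
      rt_offset_ms = rnorm(n_subjects, 0, subject_rt_sd))
  })
  grid <- condition_grid()
  rows <- vector("list", n_subjects * nrow(grid))
  idx <- 0L
  for (s in seq_len(n_subjects)) {
    for (g in seq_len(nrow(grid))) {
      cl <- grid$cl[g]; pl <- as.character(grid$pl[g])
      ef <- effect_row(effects, cl, pl)
      pars <- autonomic_params(
        mean_rr = (base_params$mean_rr + subjects$rr_offset_ms[s]) * ef$rr_mult,
        a_lf = base_params$a_lf * ef$a_lf_mult,
        a_hf = base_params$a_hf * ef$a_hf_mult,
        f_lf = base_params$f_lf, f_hf = base_params$f_hf,
        jitter_sd = base_params$jitter_sd,
        seed = child_seed(seed, "rr", s, cl, pl))
      rr <- gen_rr_series(pars, duration_s)
      logs <- lapply(seq_len(n_trials), function(tr) {
        trial <- gen_nback_sequence(cl, seed = child_seed(seed, "trial", s, cl, pl, tr))
        gen_response_log(trial, cl, pl, effects,
                         seed = child_seed(seed, "resp", s, cl, pl, tr),
                         rt_offset_ms = subjects$rt_offset_ms[s])
      })
      tlx <- gen_tlx_response(cl, pl, effects,
                              seed = child_seed(seed, "tlx", s, cl, pl))
      row <- tibble::tibble(subject = subjects$subject[s], cl = cl,
                            pl = base::factor(pl, levels = levels(pl_levels())),
                            rr = list(rr), logs = list(logs), tlx = list(tlx))
      if (include_ecg) {
        ns <- ecg_noise
        ns$seed <- child_seed(seed, "ecg", s, cl, pl)
        row$ecg <- list(gen_ecg(rr, fs = 256, noise = ns))
      }
      idx <- idx + 1L
      rows[[idx]] <- row
    }
  }
  structure(list(subjects = subjects[, c("subject", "subgroup", "task_order")],
                 records = dplyr::bind_rows(rows),
                 effects = effects, seed = seed),
            class = "study_dataset")
}

#' @export
print.study_dataset <- function(x, ...) {
  cat(sprintf("<study_dataset> %d subjects x %d conditions (seed %s)\n",
              nrow(x$subjects), nrow(x$records) / nrow(x$subjects),
              format(x$seed)))
  invisible(x)
}

#' Reduce a synthetic study dataset to a subject x condition feature table
#'
#' Computes, per subject x condition row: the 12 HRV features from the RR
#' series, the performance summary pooled over the run's trials, and the
#' weighted TLX total. This is the `ConditionTable` consumed by the
#' statistics layer.
#'
#' @param dataset a `study_dataset`.
#' @param ar_order,resample_fs spectral settings passed to [hrv_features].
#' @return A tibble: subject, cl, pl, the HRV columns, MRT/SDRT/maxRT/minRT/
#'   CNR/MNR/WNR, TLX_total.
#' @export
study_feature_table <- function(dataset, ar_order = 16L, resample_fs = 4) {
  stopifnot(inherits(dataset, "study_dataset"))
  rec <- dataset$records
  out <- vector("list", nrow(rec))
  for (i in seq_len(nrow(rec))) {
    hrv <- hrv_features(rec$rr[[i]], ar_order = ar_order,
                        resample_fs = resample_fs)
    pooled <- dplyr::bind_rows(rec$logs[[i]])
    attr(pooled, "response_window_ms") <- attr(rec$logs[[i]][[1]], "response_window_ms")
    perf <- score_performance(pooled)
    out[[i]] <- dplyr::bind_cols(
      tibble::tibble(subject = rec$subject[i], cl = rec$cl[i], pl = rec$pl[i]),
      hrv, perf[c("MRT", "SDRT", "maxRT", "minRT", "CNR", "MNR", "WNR")],
      tibble::tibble(TLX_total = score_tlx(rec$tlx[[i]])))
  }
  dplyr::bind_rows(out)
}
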