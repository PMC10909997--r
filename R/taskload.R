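#' Construct a NASA-TLX response
#'
#' Holds the six dimension ratings on the 21-point scale (stored 0-20 by
#' default; set `scale_base = 1` for 1-21 storage) and the 15 pairwise
#' importance choices, one per unordered dimension pair.
#'
#' @param ratings named numeric vector over the six dimensions
#'   (mental, physical, temporal, performance, effort, frustration).
#' @param pair_choices data frame with columns `dim_a`, `dim_b`, `choice`;
#'   exactly the 15 unordered pairs, `choice` a member of its pair.
#' @param scale_base 0 (default, ratings 0-20) or 1 (ratings 1-21).
#' @return An object of class `tlx_response`.
#' @export
tlx_response <- function(ratings, pair_choices, scale_base = 0) {
  dims <- tlx_dimensions()
  stop_if(!identical(sort(names(ratings)), sort(dims)),
          "ratings must be named over the six TLX dimensions")
  ratings <- ratings[dims]
  lo <- scale_base; hi <- scale_base + 20
  stop_if(any(ratings < lo | ratings > hi),
          "ratings must lie on the 21-point scale [", lo, ", ", hi, "]")
  pc <- as.data.frame(pair_choices)
  stop_if(!all(c("dim_a", "dim_b", "choice") %in% names(pc)),
          "pair_choices needs columns dim_a, dim_b, choice")
  stop_if(nrow(pc) != 15L, "exactly 15 pairwise choices are required")
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  expected <- utils::combn(dims, 2)
  stop_if(!setequal(key(pc$dim_a, pc$dim_b), key(expected[1, ], expected[2, ])) ||
            anyDuplicated(key(pc$dim_a, pc$dim_b)) > 0,
          "pair_choices must contain each unordered dimension pair exactly once")
  stop_if(!all(pc$choice == pc$dim_a | pc$choice == pc$dim_b),
          "each choice must be a member of its pair")
  structure(list(ratings = ratings, pair_choices = pc, scale_base = scale_base),
            class = "tlx_response")
}

#' @export
print.tlx_response <- function(x, ...) {
  cat("<tlx_response>\n")
  print(round(x$ratings, 2))
  cat(sprintf("  weighted total: %.3f\n", score_tlx(x)))
  invisible(x)
}

#' Weighted NASA-TLX total score
#'
#' Each dimension's weight is its selection frequency across the 15 pairwise
#' choices, ranked ascending and mapped to weights 1/21 ... 6/21; tied
#' dimensions receive the mean of the weights their rank positions span
#' (equivalently, weight = average rank / 21), so weights always sum to 1.
#' The total is the weight-by-rating inner product, on the rating scale.
#'
#' @param response a [tlx_response].
#' @return A single numeric: the weighted total workload score.
#' @examples
#' r <- gen_tlx_response(cl = 3, pl = "high", seed = 2)
#' score_tlx(r)
#' @export
score_tlx <- function(response) {
  stopifnot(inherits(response, "tlx_response"))
  dims <- tlx_dimensions()
  counts <- vapply(dims, function(d) sum(response$pair_choices$choice == d),
                   numeric(1))
  weights <- rank(counts, ties.method = "average") / 21
  sum(weights * response$ratings)
}

#' @rdname score_tlx
#' @export
tlx_weights <- function(response) {
  dims <- tlx_dimensions()
  counts <- vapply(dims, function(d) sum(response$pair_choices$choice == d),
                   numeric(1))
  rank(counts, ties.method = "average") / 21
}

#' Score n-back behavioral performance
#'
#' Aggregates a per-stimulus response log into the study's seven performance
#' indicators: reaction-time statistics over hits (MRT, SDRT, maxRT, minRT)
#' and the reaction ratios (CNR = hits / targets, MNR = 1 - CNR,
#' WNR = false alarms / non-targets). A hit is a response to a target within
#' the response window (target onset to next stimulus onset). RT statistics
#' are `NA` when there are no hits; SDRT uses the sample (n-1) denominator.
#'
#' @param log a `response_log` (see [gen_response_log]) or a data frame with
#'   columns `is_target`, `responded`, `rt`.
#' @param response_window_ms response window; defaults to the log's
#'   attribute, else 2000 ms.
#' @return A one-row tibble: MRT, SDRT, maxRT, minRT (ms), CNR, MNR, WNR,
#'   n_targets, n_hits.
#' @export
score_performance <- function(log, response_window_ms = NULL) {
  if (is.null(response_window_ms)) {
    response_window_ms <- attr(log, "response_window_ms") %||% 2000
  }
  stop_if(!all(c("is_target", "responded", "rt") %in% names(log)),
          "log needs columns is_target, responded, rt")
  stop_if(any(!is.na(log$rt) & !log$responded), "rt present implies responded")
  n_targets <- sum(log$is_target)
  stop_if(n_targets == 0L, "log contains no target stimuli")
  in_window <- log$responded & !is.na(log$rt) &
    log$rt > 0 & log$rt <= response_window_ms
  hits <- log$is_target & in_window
  n_hits <- sum(hits)
  n_nontargets <- sum(!log$is_target)
  cnr <- n_hits / n_targets
  wnr <- if (n_nontargets > 0) sum(!log$is_target & log$responded) / n_nontargets else NA_real_
  rts <- log$rt[hits]
  tibble::tibble(
    MRT = if (n_hits) mean(rts) else NA_real_,
    SDRT = if (n_hits > 1) sd(rts) else NA_real_,
    maxRT = if (n_hits) max(rts) else NA_real_,
    minRT = if (n_hits) min(rts) else NA_real_,
    CNR = cnr, MNR = 1 - cnr, WNR = wnr,
    n_targets = n_targets, n_hits = n_hits)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
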