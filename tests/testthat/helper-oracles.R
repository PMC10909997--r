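# Independent oracles used across the suite: deliberately naive loop-based
# re-implementations, kept free of the package's own code paths.

# exhaustive lag scan: positions i with letters[i] == letters[i - lag]
scan_lag_matches <- function(letters, lag) {
  hits <- integer(0)
  for (i in seq_along(letters)) {
    if (i > lag && letters[i] == letters[i - lag]) hits <- c(hits, i)
  }
  hits
}

# loop-based time-domain indices
oracle_time_domain <- function(x) {
  n <- length(x)
  hr <- 0
  for (v in x) hr <- hr + 60000 / v
  nn50 <- 0
  ssq <- 0
  for (i in seq_len(n - 1)) {
    d <- x[i + 1] - x[i]
    if (abs(d) > 50) nn50 <- nn50 + 1
    ssq <- ssq + d^2
  }
  m <- sum(x) / n
  sdnn <- sqrt(sum((x - m)^2) / (n - 1))
  list(meanHR = hr / n, SDNN = sdnn, NN50 = nn50,
       pNN50 = 100 * nn50 / (n - 1), RMSSD = sqrt(ssq / (n - 1)))
}

# brute-force weighted TLX total straight from the definition
oracle_tlx_total <- function(ratings, choices) {
  dims <- c("mental", "physical", "temporal", "performance", "effort", "frustration")
  counts <- sapply(dims, function(d) sum(choices == d))
  ord <- order(counts)  # ascending
  w <- numeric(6); names(w) <- dims
  pos <- 1
  while (pos <= 6) {
    tied <- which(counts == counts[ord[pos]])
    span <- pos:(pos + length(tied) - 1)
    w[tied] <- mean(span / 21)
    pos <- pos + length(tied)
  }
  sum(w * ratings[dims])
}

# loop-based performance summary
oracle_performance <- function(log, window_ms = 2000) {
  hits_rt <- c()
  n_t <- 0; n_nt <- 0; n_hit <- 0; n_fa <- 0
  for (i in seq_len(nrow(log))) {
    if (log$is_target[i]) {
      n_t <- n_t + 1
      if (log$responded[i] && !is.na(log$rt[i]) &&
          log$rt[i] > 0 && log$rt[i] <= window_ms) {
        n_hit <- n_hit + 1
        hits_rt <- c(hits_rt, log$rt[i])
      }
    } else {
      n_nt <- n_nt + 1
      if (log$responded[i]) n_fa <- n_fa + 1
    }
  }
  list(MRT = if (n_hit) mean(hits_rt) else NA_real_,
       SDRT = if (n_hit > 1) sd(hits_rt) else NA_real_,
       maxRT = if (n_hit) max(hits_rt) else NA_real_,
       minRT = if (n_hit) min(hits_rt) else NA_real_,
       CNR = n_hit / n_t, MNR = 1 - n_hit / n_t,
       WNR = if (n_nt) n_fa / n_nt else NA_real_)
}

# raw FFT power of a signal in a frequency band (one-sided), for the
# denoising attenuation checks
fft_band_power <- function(x, fs, f_lo, f_hi) {
  n <- length(x)
  p <- Mod(fft(x))^2 / n
  f <- (seq_len(n) - 1) / n * fs
  sum(p[f >= f_lo & f <= f_hi & f <= fs / 2])
}

# signed-rank statistic computed by hand: sum of ranks of |d| over positive d
oracle_signed_rank <- function(d) {
  d <- d[d != 0]
  r <- rank(abs(d))
  sum(r[d > 0])
}

# random TLX response with arbitrary (possibly tied) selection counts
random_tlx <- function(seed) {
  set.seed(seed)
  dims <- c("mental", "physical", "temporal", "performance", "effort", "frustration")
  ratings <- stats::setNames(sample(0:20, 6, replace = TRUE), dims)
  pairs <- combn(dims, 2)
  choice <- apply(pairs, 2, function(pr) sample(pr, 1))
  tlx_response(ratings, tibble::tibble(dim_a = pairs[1, ], dim_b = pairs[2, ],
                                       choice = choice))
}
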