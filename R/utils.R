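#' @importFrom stats approx ar.burg cor.test friedman.test mad median rnorm
#' @importFrom stats rlnorm runif runmed sd shapiro.test t.test var wilcox.test
#' @importFrom stats aov fft quantile rbinom
#' @importFrom utils head modifyList read.csv tail write.csv
NULL

# Evaluate expr under a local RNG state seeded with `seed`; the caller's
# .Random.seed is untouched.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

#' Derive a reproducible child seed from a parent seed and a stream label
#'
#' Hashes the parent seed together with any number of labels into a new
#' integer seed below 2^31, so one master seed can be fanned out into
#' independent, individually reproducible random streams (per subject,
#' condition, trial, ...).
#'
#' @param seed parent integer seed.
#' @param ... labels (coerced to character) identifying the substream.
#' @return An integer seed.
#' @examples
#' child_seed(1, "rr", 3, "medium")
#' @export
child_seed <- function(seed, ...) {
  lab <- paste(c(seed, ...), collapse = "/")
  h <- 0
  for (ch in utf8ToInt(lab)) h <- (h * 131 + ch) %% 2147483587
  as.integer(h)
}

# Trapezoidal integral of y over x.
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2) return(0)
  sum(diff(x) * (y[-1] + y[-n]) / 2)
}

# Reflect-pad a vector by `k` samples on each side.
reflect_pad <- function(x, k) {
  n <- length(x)
  k <- min(k, n - 1)
  c(x[(k + 1):2], x, x[(n - 1):(n - k)])
}

# Centered moving average with reflection edge handling; window in samples.
moving_average <- function(x, w) {
  w <- max(1L, as.integer(w))
  if (w %% 2 == 0) w <- w + 1L
  if (w == 1L) return(x)
  k <- (w - 1L) %/% 2L
  xp <- reflect_pad(x, k)
  out <- stats::filter(xp, rep(1 / w, w), sides = 2)
  as.numeric(out[(k + 1):(k + length(x))])
}

# Centered moving median with reflection edge handling; window in samples.
moving_median <- function(x, w) {
  w <- max(1L, as.integer(w))
  if (w %% 2 == 0) w <- w + 1L
  if (w == 1L) return(x)
  k <- (w - 1L) %/% 2L
  xp <- reflect_pad(x, k)
  out <- runmed(xp, w, endrule = "keep")
  as.numeric(out[(k + 1):(k + length(x))])
}

stop_if <- function(cond, ..., call. = FALSE) {
  if (cond) stop(..., call. = call.)
}
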