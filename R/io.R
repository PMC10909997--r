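#' Read and write pipeline artifacts as plain CSV
#'
#' All writers use comma-separated UTF-8 with a header row and '.' decimal;
#' times are in seconds, intervals in ms, powers in ms^2, with units embedded
#' in the column names. Every writer's output round-trips through its
#' reader.
#'
#' @param rr an [rr_series].
#' @param path file path.
#' @name hrvload-io
NULL

#' @rdname hrvload-io
#' @export
write_rr_csv <- function(rr, path) {
  stopifnot(inherits(rr, "rr_series"))
  df <- data.frame(beat_time_s = rr$beat_times,
                   rr_ms = c(NA, rr$intervals),
                   flag = c(NA, rr$flags))
  write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname hrvload-io
#' @export
read_rr_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  stop_if(!all(c("beat_time_s", "rr_ms") %in% names(df)),
          "not an RR CSV: need columns beat_time_s, rr_ms")
  flags <- if ("flag" %in% names(df)) df$flag[-1] else NULL
  if (!is.null(flags)) flags[is.na(flags) | flags == ""] <- "normal"
  rr_series(df$beat_time_s, df$rr_ms[-1], flags)
}

#' @rdname hrvload-io
#' @param record an [ecg_record].
#' @param write_header also write a plain-text header sidecar
#'   (`<path>.hea.txt`) carrying sampling rate, gain and units, in the
#'   spirit of a waveform-database header.
#' @export
write_ecg_csv <- function(record, path, write_header = TRUE) {
  stopifnot(inherits(record, "ecg_record"))
  n <- length(record$samples)
  df <- data.frame(time_s = (seq_len(n) - 1L) / record$fs,
                   voltage_uV = record$samples)
  write.csv(df, path, row.names = FALSE)
  if (write_header) {
    hdr <- c(sprintf("record %s", sub("\\.csv$", "", basename(path))),
             sprintf("fs_hz %g", record$fs),
             sprintf("n_samples %d", n),
             sprintf("units uV"),
             sprintf("gain 1"),
             sprintf("channel %s", record$channel_label))
    writeLines(hdr, paste0(path, ".hea.txt"))
  }
  if (!is.null(record$annotations)) {
    writeLines(format(record$annotations, digits = 12),
               paste0(path, ".ann.txt"))
  }
  invisible(path)
}

#' @rdname hrvload-io
#' @param fs sampling rate override when the header sidecar is absent.
#' @export
read_ecg_csv <- function(path, fs = NULL) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  stop_if(!all(c("time_s", "voltage_uV") %in% names(df)),
          "not an ECG CSV: need columns time_s, voltage_uV")
  hea <- paste0(path, ".hea.txt")
  if (is.null(fs)) {
    if (file.exists(hea)) {
      lines <- readLines(hea)
      fs_line <- grep("^fs_hz ", lines, value = TRUE)
      fs <- as.numeric(sub("^fs_hz ", "", fs_line[1]))
    } else {
      fs <- 1 / median(diff(df$time_s))
    }
  }
  ann_path <- paste0(path, ".ann.txt")
  ann <- if (file.exists(ann_path)) as.numeric(readLines(ann_path)) else NULL
  ecg_record(df$voltage_uV, fs, annotations = ann)
}

#' @rdname hrvload-io
#' @param log a `response_log`.
#' @export
write_response_log_csv <- function(log, path) {
  df <- as.data.frame(log)
  df$response_window_ms <- attr(log, "response_window_ms") %||% 2000
  write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname hrvload-io
#' @export
read_response_log_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  win <- df$response_window_ms[1]
  out <- tibble::as_tibble(df[c("onset", "is_target", "responded", "rt")])
  attr(out, "response_window_ms") <- win
  class(out) <- c("response_log", class(out))
  out
}

#' @rdname hrvload-io
#' @param response a [tlx_response].
#' @export
write_tlx_csv <- function(response, path) {
  stopifnot(inherits(response, "tlx_response"))
  ratings <- data.frame(kind = "rating", dim_a = names(response$ratings),
                        dim_b = "", choice = "",
                        value = unname(response$ratings))
  pairs <- data.frame(kind = "pair", dim_a = response$pair_choices$dim_a,
                      dim_b = response$pair_choices$dim_b,
                      choice = response$pair_choices$choice, value = NA)
  write.csv(rbind(ratings, pairs), path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname hrvload-io
#' @export
read_tlx_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  r <- df[df$kind == "rating", ]
  ratings <- stats::setNames(r$value, r$dim_a)
  p <- df[df$kind == "pair", ]
  tlx_response(ratings, tibble::tibble(dim_a = p$dim_a, dim_b = p$dim_b,
                                       choice = p$choice))
}
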