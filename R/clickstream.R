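#' Construct a click stream
#'
#' A click stream is the package's common currency: a time-ordered table of
#' logged acoustic transients ("pings"), whether exported from a click logger,
#' detected in raw audio, or simulated. Each event carries the four attributes
#' a POD-style logger stores per click: time, carrier frequency, duration in
#' carrier cycles, and linear amplitude (arbitrary units — only ratios are
#' ever used downstream).
#'
#' @param events data.frame with numeric columns `time_s`, `freq_khz`,
#'   `n_cycles`, `amplitude`. Rows may arrive in any order; they are sorted by
#'   `time_s`.
#' @param source one of `"pod"`, `"audio"`, `"synthetic"`: where the events
#'   came from.
#' @param stream_id free-text label carried through for provenance.
#' @param duration_s total span covered by the stream. Defaults to the last
#'   event time (0 for an empty stream). Must be >= every event time.
#' @return An object of class `click_stream`: a list with elements `events`
#'   (sorted data.frame), `source`, `stream_id`, `duration_s`.
#' @seealso [read_clickstream()], [band_cycle_filter()], [find_packets()]
#' @export
#' @examples
#' ev <- data.frame(time_s = c(1, 0.5), freq_khz = 69.5,
#'                  n_cycles = 40, amplitude = 1)
#' cs <- click_stream(ev, source = "synthetic")
#' cs$events$time_s  # sorted: 0.5 1.0
click_stream <- function(events, source = c("pod", "audio", "synthetic"),
                         stream_id = "", duration_s = NULL) {
  source <- match.arg(source)
  cols <- c("time_s", "freq_khz", "n_cycles", "amplitude")
  if (!is.data.frame(events) || !all(cols %in% names(events))) {
    stop("`events` must be a data.frame with columns ",
         paste(cols, collapse = ", "), call. = FALSE)
  }
  events <- events[cols]
  for (cl in cols) {
    events[[cl]] <- as.numeric(events[[cl]])
    if (anyNA(events[[cl]])) {
      stop("non-numeric or missing values in column '", cl, "'",
           call. = FALSE)
    }
  }
  if (nrow(events)) {
    if (any(events$time_s < 0)) stop("event time_s must be >= 0", call. = FALSE)
    if (any(events$freq_khz <= 0)) stop("freq_khz must be > 0", call. = FALSE)
    if (any(events$n_cycles < 1)) stop("n_cycles must be >= 1", call. = FALSE)
    if (any(events$amplitude <= 0)) stop("amplitude must be > 0", call. = FALSE)
    events <- events[order(events$time_s), , drop = FALSE]
    rownames(events) <- NULL
  }
  last <- if (nrow(events)) max(events$time_s) else 0
  if (is.null(duration_s)) duration_s <- last
  if (duration_s < last) {
    stop("duration_s (", duration_s, ") is smaller than the last event time (",
         last, ")", call. = FALSE)
  }
  structure(list(events = events, source = source, stream_id = stream_id,
                 duration_s = duration_s),
            class = "click_stream")
}

#' @export
print.click_stream <- function(x, ...) {
  cat(sprintf("<click_stream '%s' [%s]: %d events over %.3f s>\n",
              x$stream_id, x$source, nrow(x$events), x$duration_s))
  invisible(x)
}

empty_events <- function() {
  data.frame(time_s = numeric(), freq_khz = numeric(),
             n_cycles = numeric(), amplitude = numeric())
}

#' Read a click-event table
#'
#' Reads the CSV interchange format for click-event logs: header
#' `time_s,freq_khz,n_cycles,amplitude`, one row per logged ping, comma
#' separated, decimal point `.`. Rows may be in any order; the returned stream
#' is sorted by time.
#'
#' @param path path to a CSV file.
#' @param source_label stream provenance, passed to [click_stream()]
#'   (default `"pod"`).
#' @param stream_id label for the stream; defaults to the file name.
#' @return A [click_stream()] with `duration_s` equal to the last event time
#'   (0 when the file has no data rows).
#' @export
read_clickstream <- function(path, source_label = "pod",
                             stream_id = basename(path)) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- tryCatch(
    read.csv(path, colClasses = "character", strip.white = TRUE),
    error = function(e) stop("parse error in '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  cols <- c("time_s", "freq_khz", "n_cycles", "amplitude")
  if (!identical(names(raw), cols)) {
    stop("parse error in '", path, "': expected header ",
         paste(cols, collapse = ","), call. = FALSE)
  }
  ev <- empty_events()
  if (nrow(raw)) {
    num <- lapply(raw, function(x) suppressWarnings(as.numeric(x)))
    bad <- Reduce(`|`, lapply(num, is.na))
    if (any(bad)) {
      stop("parse error in '", path, "' at line ",
           which(bad)[1] + 1L, ": malformed row", call. = FALSE)
    }
    ev <- as.data.frame(num)
  }
  click_stream(ev, source = source_label, stream_id = stream_id)
}

#' Write a click-event table
#'
#' Companion writer for [read_clickstream()]: emits the standard CSV schema
#' with times at microsecond (6 d.p.) precision.
#'
#' @param stream a [click_stream()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_clickstream <- function(stream, path) {
  stopifnot(inherits(stream, "click_stream"))
  ev <- stream$events
  out <- data.frame(time_s = sprintf("%.6f", ev$time_s),
                    freq_khz = sprintf("%.3f", ev$freq_khz),
                    n_cycles = sprintf("%.3f", ev$n_cycles),
                    amplitude = sprintf("%.6g", ev$amplitude))
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export code packets as tab-separated text
#'
#' Writes one packet per line — first ping time, the 7 inter-ping intervals
#' (6 d.p., seconds) and the quality score (1 d.p.) — the "simple text format
#' that can be pasted into a spreadsheet" style of export. Round-trips through
#' [read_packets_text()] at the stated precision.
#'
#' @param packets list of code packets as returned by [find_packets()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_packets_text <- function(packets, path) {
  lines <- c(paste(c("first_ping_time_s", paste0("interval_", 1:7), "score"),
                   collapse = "\t"))
  for (p in packets) {
    if (!inherits(p, "code_packet")) {
      stop("`packets` must be a list of code_packet objects", call. = FALSE)
    }
    if (length(p$intervals_s) != 7L) {
      stop("packet does not carry 8 pings (7 intervals); got ",
           length(p$intervals_s), " intervals", call. = FALSE)
    }
    lines <- c(lines, paste(c(sprintf("%.6f", p$first_ping_time_s),
                              sprintf("%.6f", p$intervals_s),
                              sprintf("%.1f", p$score)),
                            collapse = "\t"))
  }
  ok <- tryCatch({ writeLines(lines, path); TRUE },
                 error = function(e) FALSE, warning = function(e) FALSE)
  if (!ok) stop("cannot write packet export to '", path, "'", call. = FALSE)
  invisible(path)
}

#' Read a packet export written by [write_packets_text()]
#'
#' @param path packet export path.
#' @return A list of `code_packet` objects. Ping amplitudes are not stored in
#'   the export, so `n_stray` and `amp_cv` are `NA` on re-read.
#' @export
read_packets_text <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  if (!length(lines)) stop("parse error in '", path, "': empty file",
                           call. = FALSE)
  out <- list()
  for (i in seq_along(lines)[-1]) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) != 9L) {
      stop("parse error in '", path, "' at line ", i,
           ": expected 9 tab-separated fields", call. = FALSE)
    }
    v <- suppressWarnings(as.numeric(f))
    if (anyNA(v)) {
      stop("parse error in '", path, "' at line ", i, ": non-numeric field",
           call. = FALSE)
    }
    t0 <- v[1]
    out[[length(out) + 1L]] <- code_packet(
      ping_times_s = t0 + cumsum(c(0, v[2:8])),
      score = v[9], n_stray = NA_real_, amp_cv = NA_real_)
  }
  out
}

#' Tabulate a list of code packets
#'
#' @param packets list of `code_packet` objects.
#' @return data.frame with one row per packet: first ping time, the seven
#'   intervals, score, stray count and amplitude CV.
#' @export
packets_to_data_frame <- function(packets) {
  if (!length(packets)) {
    df <- as.data.frame(matrix(numeric(), ncol = 11,
                               dimnames = list(NULL, c(
                                 "first_ping_time_s", paste0("interval_", 1:7),
                                 "score", "n_stray", "amp_cv"))))
    return(df)
  }
  do.call(rbind, lapply(packets, function(p) {
    d <- as.data.frame(as.list(stats::setNames(p$intervals_s,
                                               paste0("interval_", 1:7))))
    cbind(data.frame(first_ping_time_s = p$first_ping_time_s), d,
          data.frame(score = p$score, n_stray = p$n_stray, amp_cv = p$amp_cv))
  }))
}
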