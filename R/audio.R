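#' Audio ping-detector configuration
#'
#' Parameters of the automated raw-audio route: band-pass around the tag
#' carrier, envelope thresholding, run merging and a minimum ping duration.
#'
#' @param center_khz band center frequency (kHz).
#' @param half_band_khz half-width of the pass band (kHz).
#' @param envelope_threshold detection threshold on the analytic envelope. In
#'   `"fraction"` mode (default) it is a fraction of the segment's maximum
#'   envelope; in `"absolute"` mode it is a linear sample level.
#' @param threshold_mode `"fraction"` or `"absolute"`.
#' @param min_ping_duration_s discard super-threshold runs shorter than this.
#' @param merge_gap_s merge super-threshold runs separated by less than this.
#' @return A classed list (`audio_detector_config`).
#' @export
audio_detector_config <- function(center_khz = 69.0, half_band_khz = 3.0,
                                  envelope_threshold = 0.1,
                                  threshold_mode = c("fraction", "absolute"),
                                  min_ping_duration_s = 0.002,
                                  merge_gap_s = 0.001) {
  threshold_mode <- match.arg(threshold_mode)
  if (threshold_mode == "fraction" &&
      (envelope_threshold <= 0 || envelope_threshold >= 1)) {
    stop("fractional envelope_threshold must lie in (0, 1)", call. = FALSE)
  }
  structure(list(center_khz = center_khz, half_band_khz = half_band_khz,
                 envelope_threshold = envelope_threshold,
                 threshold_mode = threshold_mode,
                 min_ping_duration_s = min_ping_duration_s,
                 merge_gap_s = merge_gap_s),
            class = "audio_detector_config")
}

#' Validate an audio segment for tag-packet work
#'
#' Tag carriers sit near 69 kHz, so recordings must be sampled at 140 kS/s or
#' faster to contain the packet information at all.
#'
#' @param segment an [audio_segment()].
#' @return `TRUE` invisibly; errors below the minimum rate.
#' @export
validate_audio <- function(segment) {
  stopifnot(inherits(segment, "audio_segment"))
  if (segment$sample_rate_hz < 140000) {
    stop("unsupported sample rate ", segment$sample_rate_hz,
         " Hz: tag detection requires at least 140000 Hz", call. = FALSE)
  }
  invisible(TRUE)
}

# Analytic signal via the half-spectrum construction; zero-padded to a
# 2-3-5-smooth length so the FFT stays O(n log n) for awkward lengths.
analytic_signal <- function(x) {
  n <- length(x)
  m <- stats::nextn(n, c(2, 3, 5))
  xp <- c(x, numeric(m - n))
  X <- fft(xp)
  h <- numeric(m)
  if (m %% 2 == 0) {
    h[1] <- 1; h[m / 2 + 1] <- 1; h[2:(m / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((m + 1) / 2)] <- 2
  }
  z <- fft(X * h, inverse = TRUE) / m
  z[seq_len(n)]
}

# Band-pass around the tag carrier: 4th-order Butterworth, applied
# forwards-backwards (zero phase). Rejection one octave off-center is far
# beyond the 40 dB contract.
bandpass_carrier <- function(x, fs, center_khz, half_band_khz) {
  lo <- (center_khz - half_band_khz) * 1000
  hi <- (center_khz + half_band_khz) * 1000
  nyq <- fs / 2
  if (lo <= 0 || hi >= nyq) {
    stop("pass band ", lo, "-", hi, " Hz does not fit below Nyquist (",
         nyq, " Hz)", call. = FALSE)
  }
  bf <- signal::butter(4, c(lo, hi) / nyq, type = "pass")
  as.numeric(signal::filtfilt(bf, x))
}

# Dominant frequency (Hz) of a sample run by spectral peak, zero-padded for
# resolution.
dominant_freq <- function(x, fs) {
  n <- length(x)
  nfft <- max(8192L, stats::nextn(n, 2))
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(n) / (n + 1))  # Hann
  X <- Mod(fft(c(x * w, numeric(nfft - n))))
  half <- X[2:(nfft %/% 2)]  # skip DC
  k <- which.max(half)
  k * fs / nfft
}

#' Detect tag pings in raw audio
#'
#' Automated replacement for manual spectrogram screening. Pipeline: band-pass
#' the signal to `center_khz` +/- `half_band_khz`; compute the analytic
#' envelope; threshold it; merge super-threshold runs separated by less than
#' `merge_gap_s`; discard runs shorter than `min_ping_duration_s`; emit one
#' event per surviving run. The event time is the envelope-energy centroid of
#' the run (identical to the envelope peak for symmetric pings, and
#' well-defined for the flat-topped bursts tags emit), the amplitude is the
#' peak envelope, the frequency is the run's spectral peak quantized to
#' 0.25 kHz (sub-bin precision is spurious for millisecond transients, and
#' the quantization keeps a 69 kHz carrier from straddling the inclusive
#' 69 kHz band edge downstream), and the cycle count is the run duration
#' times that frequency.
#'
#' @param segment an [audio_segment()] at >= 140 kS/s.
#' @param cfg an [audio_detector_config()].
#' @return A [click_stream()] with `source = "audio"`; empty for silent or
#'   sub-threshold input.
#' @export
detect_pings <- function(segment, cfg = audio_detector_config()) {
  validate_audio(segment)
  fs <- segment$sample_rate_hz
  x <- segment$samples
  if (!length(x) || all(x == 0)) {
    return(click_stream(empty_events(), source = "audio",
                        stream_id = "audio",
                        duration_s = segment$start_offset_s +
                          length(x) / fs))
  }
  xb <- bandpass_carrier(x, fs, cfg$center_khz, cfg$half_band_khz)
  env <- Mod(analytic_signal(xb))
  thr <- if (cfg$threshold_mode == "fraction") {
    cfg$envelope_threshold * max(env)
  } else {
    cfg$envelope_threshold
  }
  above <- env >= thr
  if (!any(above)) {
    return(click_stream(empty_events(), source = "audio",
                        stream_id = "audio",
                        duration_s = segment$start_offset_s +
                          length(x) / fs))
  }
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- cbind(starts[r$values], ends[r$values])
  # merge runs separated by a short sub-threshold gap
  gap_n <- cfg$merge_gap_s * fs
  if (nrow(runs) > 1) {
    merged <- runs[1, , drop = FALSE]
    for (k in 2:nrow(runs)) {
      if (runs[k, 1] - merged[nrow(merged), 2] - 1L < gap_n) {
        merged[nrow(merged), 2] <- runs[k, 2]
      } else {
        merged <- rbind(merged, runs[k, ])
      }
    }
    runs <- merged
  }
  keep <- (runs[, 2] - runs[, 1] + 1L) / fs >= cfg$min_ping_duration_s
  runs <- runs[keep, , drop = FALSE]
  if (!nrow(runs)) {
    return(click_stream(empty_events(), source = "audio",
                        stream_id = "audio",
                        duration_s = segment$start_offset_s +
                          length(x) / fs))
  }
  ev <- do.call(rbind, lapply(seq_len(nrow(runs)), function(k) {
    i0 <- runs[k, 1]; i1 <- runs[k, 2]
    e <- env[i0:i1]
    idx <- i0:i1
    centroid <- sum(e^2 * idx) / sum(e^2)
    f_hz <- dominant_freq(xb[i0:i1], fs)
    dur <- (i1 - i0 + 1L) / fs
    data.frame(time_s = segment$start_offset_s + (centroid - 1) / fs,
               freq_khz = round(f_hz / 250) * 0.25,
               n_cycles = dur * f_hz,
               amplitude = max(e))
  }))
  click_stream(ev, source = "audio", stream_id = "audio",
               duration_s = max(segment$start_offset_s + length(x) / fs,
                                max(ev$time_s)))
}

#' Extract a single-ping waveform template
#'
#' Copies a window around a detected ping out of a recording and
#' peak-normalizes it to 0.9, giving the template that reconstruction pastes
#' at each recovered ping time.
#'
#' @param segment source [audio_segment()].
#' @param ping_time_s center of the window (seconds, in the segment's time
#'   base).
#' @param duration_s window length; the window is
#'   `ping_time_s +/- duration_s/2` and must lie inside the segment.
#' @return An [audio_segment()] at the source rate, `start_offset_s = 0`,
#'   peak 0.9.
#' @export
extract_ping_template <- function(segment, ping_time_s, duration_s) {
  stopifnot(inherits(segment, "audio_segment"))
  fs <- segment$sample_rate_hz
  t0 <- ping_time_s - duration_s / 2 - segment$start_offset_s
  t1 <- ping_time_s + duration_s / 2 - segment$start_offset_s
  i0 <- floor(t0 * fs) + 1L
  i1 <- ceiling(t1 * fs)
  if (i0 < 1L || i1 > length(segment$samples)) {
    stop("template window [", round(t0, 6), ", ", round(t1, 6),
         "] s lies outside the segment", call. = FALSE)
  }
  x <- segment$samples[i0:i1]
  pk <- max(abs(x))
  if (pk == 0) stop("template window contains only silence", call. = FALSE)
  audio_segment(x * (0.9 / pk), fs)
}
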