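#' Reconstruction configuration
#'
#' Controls rebuilding of playable code-packet files: a baseline file of at
#' least 5 s at 384 kHz, the first ping placed 1000 ms in (the lead-in guards
#' against start-of-file playback artefacts), and a silent or noise baseline.
#'
#' @param output_rate_hz output sampling rate (Hz).
#' @param lead_in_s time of the first ping peak (seconds).
#' @param min_duration_s minimum output file duration (seconds); extended when
#'   the packet plus tail does not fit.
#' @param baseline `"silence"` (default) or `"noise"` — white Gaussian
#'   baseline at `noise_rms`.
#' @param noise_rms RMS of the noise baseline (linear, ignored for silence).
#' @return A classed list (`reconstruction_config`).
#' @export
reconstruction_config <- function(output_rate_hz = 384000, lead_in_s = 1.0,
                                  min_duration_s = 5.0,
                                  baseline = c("silence", "noise"),
                                  noise_rms = 0) {
  baseline <- match.arg(baseline)
  if (lead_in_s < 0) stop("lead_in_s must be >= 0", call. = FALSE)
  if (min_duration_s <= lead_in_s) {
    stop("min_duration_s must exceed lead_in_s", call. = FALSE)
  }
  structure(list(output_rate_hz = as.integer(output_rate_hz),
                 lead_in_s = lead_in_s, min_duration_s = min_duration_s,
                 baseline = baseline, noise_rms = noise_rms),
            class = "reconstruction_config")
}

# Envelope-energy centroid of a template, in (fractional) samples from its
# first sample. Placement and detection share this convention, so recovered
# intervals are independent of it.
template_peak_sample <- function(samples) {
  e <- Mod(analytic_signal(samples))
  sum(e^2 * (seq_along(e) - 1)) / sum(e^2)
}

#' Rebuild a code-packet waveform from intervals and a ping template
#'
#' Creates a baseline file (default 5 s at 384 kHz) and pastes the ping
#' template 8 times: the first ping's envelope peak at `lead_in_s`
#' (T = 1000 ms by default), each following ping offset by the corresponding
#' recovered interval, each placement rounded to the nearest sample. The
#' result is playable to any PPM decoder, hardware or [decode_intervals()].
#'
#' @param template single-ping [audio_segment()] (use
#'   [extract_ping_template()] or [make_ping_template()]); must be shorter
#'   than the smallest interval. Resampled if its rate differs from
#'   `output_rate_hz`.
#' @param intervals_s the 7 positive inter-ping intervals (seconds).
#' @param cfg a [reconstruction_config()].
#' @return An [audio_segment()] of duration
#'   `max(min_duration_s, lead_in_s + sum(intervals) + template + 0.5 s tail)`
#'   with samples clipped to \[-1, 1\].
#' @export
reconstruct_packet_audio <- function(template, intervals_s,
                                     cfg = reconstruction_config()) {
  stopifnot(inherits(template, "audio_segment"))
  intervals_s <- as.numeric(intervals_s)
  if (length(intervals_s) != 7L || any(intervals_s <= 0)) {
    stop("intervals_s must be 7 positive reals", call. = FALSE)
  }
  if (!length(template$samples)) stop("empty template", call. = FALSE)
  fs <- cfg$output_rate_hz
  tpl <- template$samples
  if (template$sample_rate_hz != fs) {
    n_new <- max(2L, round(length(tpl) * fs / template$sample_rate_hz))
    tpl <- approx(x = seq_along(tpl), y = tpl,
                  xout = seq(1, length(tpl), length.out = n_new))$y
  }
  tpl_dur <- length(tpl) / fs
  if (tpl_dur >= min(intervals_s)) {
    stop("template duration (", round(tpl_dur, 4),
         " s) is not shorter than the smallest interval (",
         round(min(intervals_s), 4), " s): pings would overlap",
         call. = FALSE)
  }
  duration <- max(cfg$min_duration_s,
                  cfg$lead_in_s + sum(intervals_s) + tpl_dur + 0.5)
  n <- round(duration * fs)
  out <- if (cfg$baseline == "noise" && cfg$noise_rms > 0) {
    rnorm(n, 0, cfg$noise_rms)
  } else {
    numeric(n)
  }
  peak <- template_peak_sample(tpl)
  times <- cfg$lead_in_s + cumsum(c(0, intervals_s))
  for (tk in times) {
    i0 <- round(tk * fs - peak) + 1L
    idx <- i0:(i0 + length(tpl) - 1L)
    ok <- idx >= 1L & idx <= n
    out[idx[ok]] <- out[idx[ok]] + tpl[ok]
  }
  audio_segment(pmax(-1, pmin(1, out)), fs)
}

#' Reconstruct one WAV per recovered packet
#'
#' @param packets list of [code_packet()] objects.
#' @param template single-ping [audio_segment()].
#' @param cfg a [reconstruction_config()].
#' @param out_dir output directory (created if absent).
#' @return Character vector of written file paths, in packet order. Files are
#'   named `packet_<first ping time, 3 d.p.>.wav`; name collisions get an
#'   `_<index>` suffix.
#' @export
batch_reconstruct <- function(packets, template,
                              cfg = reconstruction_config(), out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  paths <- character(0)
  seen <- character(0)
  for (p in packets) {
    base <- sprintf("packet_%.3f", p$first_ping_time_s)
    name <- base
    k <- 0L
    while (name %in% seen) {
      k <- k + 1L
      name <- sprintf("%s_%d", base, k)
    }
    seen <- c(seen, name)
    path <- file.path(out_dir, paste0(name, ".wav"))
    wav <- reconstruct_packet_audio(template, p$intervals_s, cfg)
    write_wav(wav, path)
    paths <- c(paths, path)
  }
  paths
}

#' Synthesize a canonical single-ping template
#'
#' A gated sinusoid at the tag carrier with raised-cosine on/off ramps,
#' peak-normalized to 0.9 — the idealized shape of a tag ping, usable in place
#' of a template extracted from a recording.
#'
#' @param sample_rate_hz template rate (Hz, >= 140000).
#' @param freq_khz carrier frequency (kHz).
#' @param duration_s ping duration (seconds).
#' @param ramp_s raised-cosine ramp length at each end (seconds).
#' @return An [audio_segment()].
#' @export
make_ping_template <- function(sample_rate_hz = 384000, freq_khz = 69,
                               duration_s = 0.005, ramp_s = 0.0005) {
  n <- round(duration_s * sample_rate_hz)
  t <- (seq_len(n) - 1) / sample_rate_hz
  env <- rep(1, n)
  nr <- round(ramp_s * sample_rate_hz)
  if (nr > 0 && 2 * nr <= n) {
    ramp <- 0.5 - 0.5 * cos(pi * seq_len(nr) / nr)
    env[seq_len(nr)] <- ramp
    env[(n - nr + 1):n] <- rev(ramp)
  }
  audio_segment(0.9 * env * sin(2 * pi * freq_khz * 1000 * t),
                sample_rate_hz)
}
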