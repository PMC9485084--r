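#' Define a simulation scenario
#'
#' One tag transmitting periodically at a fixed range from one receiver, with
#' sonar-equation propagation (log-law spreading plus linear absorption),
#' optional multipath echoes, per-ping level fading, and Poisson background
#' clutter. The same scenario drives both the click-stream route
#' ([gen_clickstream()]) and the raw-audio route ([gen_audio()]), which share
#' the seeded truth so the two routes can be compared packet for packet.
#'
#' Seeding: `seed` is the master seed. Tag timing/jitter/fading draw from
#' `seed`, clutter from `seed + 500009`, audio noise from `seed + 900007`
#' (all reduced modulo 2^31 - 1), so changing e.g. the clutter rate never
#' perturbs the tag transmissions.
#'
#' @param tag_id tag identity to encode (see [codemap_id_space()]).
#' @param codemap a [ppm_codemap()].
#' @param transmit_period_s seconds between packet starts (range-test tags
#'   use 10 s; towed-array test tags 60 s). Must exceed the packet span.
#' @param source_level_db source level, dB re 1 uPa at 1 m (V9-class tags are
#'   around 147 dB).
#' @param ping_duration_s per-ping duration (5 ms default, i.e. ~345 carrier
#'   cycles at 69 kHz — far above the 5-cycle filter floor).
#' @param range_m tag-to-receiver range, metres (>= 1).
#' @param spreading_coeff spreading-law coefficient (20 = spherical).
#' @param absorption_db_per_m absorption, dB per metre (0.025 is the right
#'   order for ~69 kHz in seawater).
#' @param multipath_echoes data.frame with columns `delay_s`, `rel_db`
#'   (negative = weaker than the direct path); one echo event per ping per
#'   row. `NULL` for none.
#' @param detection_threshold_db received level (dB) below which the click
#'   logger does not register a ping.
#' @param fading_sd_db SD of per-ping Gaussian received-level fading (dB);
#'   0 = deterministic propagation.
#' @param clutter_rate_hz Poisson rate of background clicks.
#' @param clutter_freq_range_khz frequency range of clutter clicks.
#' @param clutter_level_db mean received level of clutter clicks (dB; 6 dB SD
#'   lognormal spread).
#' @param duration_s scenario length, seconds.
#' @param start_phase_s time of the first packet start; `NULL` (default)
#'   draws it uniformly on `[0, transmit_period_s)`.
#' @param audio_rate_hz sampling rate for [gen_audio()] (>= 140000).
#' @param noise_rms additive white-noise RMS for [gen_audio()].
#' @param full_scale_db received level mapped to digital full scale in
#'   [gen_audio()].
#' @param seed master seed (integer).
#' @return A classed list (`sim_scenario`).
#' @export
scenario <- function(tag_id, codemap = default_codemap(),
                     transmit_period_s = 10, source_level_db = 147,
                     ping_duration_s = 0.005, range_m = 5,
                     spreading_coeff = 20, absorption_db_per_m = 0.025,
                     multipath_echoes = NULL,
                     detection_threshold_db = 90, fading_sd_db = 0,
                     clutter_rate_hz = 0,
                     clutter_freq_range_khz = c(20, 160),
                     clutter_level_db = 105,
                     duration_s = 60, start_phase_s = NULL,
                     audio_rate_hz = 384000, noise_rms = 0.001,
                     full_scale_db = 135, seed = 1L) {
  if (range_m < 1) stop("range_m must be >= 1", call. = FALSE)
  intervals <- encode_tag(tag_id, codemap)  # validates tag_id
  span <- sum(intervals)
  if (transmit_period_s <= span) {
    stop("transmit_period_s (", transmit_period_s,
         ") must exceed the packet span (", round(span, 3), " s)",
         call. = FALSE)
  }
  if (audio_rate_hz < 140000) {
    stop("audio_rate_hz must be >= 140000", call. = FALSE)
  }
  structure(list(tag_id = as.integer(tag_id), codemap = codemap,
                 transmit_period_s = transmit_period_s,
                 source_level_db = source_level_db,
                 ping_duration_s = ping_duration_s, range_m = range_m,
                 spreading_coeff = spreading_coeff,
                 absorption_db_per_m = absorption_db_per_m,
                 multipath_echoes = multipath_echoes,
                 detection_threshold_db = detection_threshold_db,
                 fading_sd_db = fading_sd_db,
                 clutter_rate_hz = clutter_rate_hz,
                 clutter_freq_range_khz = clutter_freq_range_khz,
                 clutter_level_db = clutter_level_db,
                 duration_s = duration_s, start_phase_s = start_phase_s,
                 audio_rate_hz = as.integer(audio_rate_hz),
                 noise_rms = noise_rms, full_scale_db = full_scale_db,
                 seed = as.integer(seed)),
            class = "sim_scenario")
}

#' Transmission loss of the propagation model
#'
#' `loss = spreading_coeff * log10(range) + absorption * range` (dB) — the
#' standard sonar-equation form: log-law spreading plus linear absorption.
#' Strictly increasing in range.
#'
#' @param range_m range in metres (>= 1).
#' @param spreading_coeff spreading-law coefficient.
#' @param absorption_db_per_m absorption coefficient, dB/m.
#' @return loss in dB.
#' @export
#' @examples
#' transmission_loss(1)    # 0.025 dB (absorption only)
#' transmission_loss(100)  # 42.5 dB
transmission_loss <- function(range_m, spreading_coeff = 20,
                              absorption_db_per_m = 0.025) {
  if (any(range_m < 1)) stop("range_m must be >= 1", call. = FALSE)
  spreading_coeff * log10(range_m) + absorption_db_per_m * range_m
}

# dB received level -> linear amplitude in the click-stream's arbitrary units
.rl_to_amp <- function(rl_db) 10^(rl_db / 20) * 1e-6

# Seeded ground truth shared by the click-stream and audio routes: packet
# start times, per-ping times/frequencies/received levels for direct paths
# and echoes, and the clutter table.
gen_truth <- function(scen) {
  stopifnot(inherits(scen, "sim_scenario"))
  intervals <- encode_tag(scen$tag_id, scen$codemap)
  offsets <- cumsum(c(0, intervals))
  span <- offsets[length(offsets)]
  tl <- transmission_loss(scen$range_m, scen$spreading_coeff,
                          scen$absorption_db_per_m)

  tag <- with_seed(scen$seed, {
    phase <- scen$start_phase_s %||% runif(1, 0, scen$transmit_period_s)
    starts <- if (phase > scen$duration_s) numeric(0) else {
      seq(phase, scen$duration_s, by = scen$transmit_period_s)
    }
    times <- as.vector(outer(offsets, starts, `+`))
    keep <- times <= scen$duration_s
    np <- length(times)
    freq <- 69 + runif(np, -0.2, 0.2)
    fade <- if (scen$fading_sd_db > 0) rnorm(np, 0, scen$fading_sd_db)
            else numeric(np)
    list(phase = phase, starts = starts,
         pings = data.frame(time_s = times, freq_khz = freq,
                            rl_db = scen$source_level_db - tl + fade,
                            packet = rep(seq_along(starts),
                                         each = length(offsets)))[keep, ,
                                                                  drop = FALSE])
  })

  echoes <- NULL
  if (!is.null(scen$multipath_echoes) && nrow(scen$multipath_echoes)) {
    echoes <- do.call(rbind, lapply(seq_len(nrow(scen$multipath_echoes)),
                                    function(k) {
      e <- scen$multipath_echoes[k, ]
      data.frame(time_s = tag$pings$time_s + e$delay_s,
                 freq_khz = tag$pings$freq_khz,
                 rl_db = tag$pings$rl_db + e$rel_db,
                 packet = tag$pings$packet)
    }))
    echoes <- echoes[echoes$time_s <= scen$duration_s, , drop = FALSE]
  }

  clutter <- with_seed(scen$seed + 500009, {
    n_cl <- rpois(1, scen$clutter_rate_hz * scen$duration_s)
    data.frame(time_s = sort(runif(n_cl, 0, scen$duration_s)),
               freq_khz = runif(n_cl, scen$clutter_freq_range_khz[1],
                                scen$clutter_freq_range_khz[2]),
               rl_db = scen$clutter_level_db + rnorm(n_cl, 0, 6),
               n_cycles = runif(n_cl, 2, 60))
  })

  truth <- data.frame(packet_time_s = tag$starts,
                      tag_id = rep(scen$tag_id, length(tag$starts)),
                      complete = tag$starts + span <= scen$duration_s)
  list(truth = truth, pings = tag$pings, echoes = echoes, clutter = clutter,
       intervals = intervals, span = span, tl_db = tl)
}

#' Generate a synthetic click stream
#'
#' Emulates what a click logger at the scenario's range would record: tag
#' pings (with seeded frequency jitter <= 0.2 kHz and optional level fading)
#' attenuated by [transmission_loss()] and dropped below the detection
#' threshold, per-ping multipath echoes, and Poisson clutter clicks.
#' Bit-identical for identical seeds.
#'
#' @param scen a [scenario()].
#' @return A list: `stream` (a [click_stream()], `source = "synthetic"`) and
#'   `truth` (data.frame `packet_time_s`, `tag_id`, `complete` — one row per
#'   transmitted packet; `complete` marks packets whose full span fits inside
#'   the scenario duration).
#' @export
gen_clickstream <- function(scen) {
  g <- gen_truth(scen)
  thr <- scen$detection_threshold_db

  # Loggers estimate frequency by cycle counting at coarse resolution; the
  # logged value is quantized to 0.5 kHz so sub-kHz measurement jitter on a
  # 69 kHz carrier never strays below the inclusive 69 kHz band edge. The
  # raw jittered estimate stays visible through n_cycles.
  q_khz <- function(f) round(f * 2) / 2
  parts <- list()
  tp <- g$pings[g$pings$rl_db >= thr, , drop = FALSE]
  if (nrow(tp)) {
    parts$tag <- data.frame(time_s = tp$time_s, freq_khz = q_khz(tp$freq_khz),
                            n_cycles = scen$ping_duration_s * tp$freq_khz *
                              1000,
                            amplitude = .rl_to_amp(tp$rl_db))
  }
  if (!is.null(g$echoes)) {
    ep <- g$echoes[g$echoes$rl_db >= thr, , drop = FALSE]
    if (nrow(ep)) {
      parts$echo <- data.frame(time_s = ep$time_s,
                               freq_khz = q_khz(ep$freq_khz),
                               n_cycles = scen$ping_duration_s *
                                 ep$freq_khz * 1000,
                               amplitude = .rl_to_amp(ep$rl_db))
    }
  }
  cl <- g$clutter[g$clutter$rl_db >= thr, , drop = FALSE]
  if (nrow(cl)) {
    parts$clutter <- data.frame(time_s = cl$time_s,
                                freq_khz = q_khz(cl$freq_khz),
                                n_cycles = cl$n_cycles,
                                amplitude = .rl_to_amp(cl$rl_db))
  }
  ev <- if (length(parts)) do.call(rbind, parts) else empty_events()
  stream <- click_stream(ev, source = "synthetic",
                         stream_id = sprintf("sim-tag%d-seed%d",
                                             scen$tag_id, scen$seed),
                         duration_s = scen$duration_s)
  list(stream = stream, truth = g$truth)
}

#' Generate synthetic raw audio
#'
#' Renders the same seeded truth as [gen_clickstream()] as a waveform: each
#' ping (direct path and echoes) becomes a gated sinusoid at the 69 kHz
#' carrier with 0.5 ms raised-cosine ramps, centered on the truth ping time
#' (so its envelope peak sits at the truth time), with peak amplitude
#' `10^((received level - full_scale_db)/20)`; white Gaussian noise at
#' `noise_rms` is added. No detection threshold is applied — thresholding is
#' the detector's job on this route. Deterministic given the seed.
#'
#' @param scen a [scenario()].
#' @return A list: `audio` (an [audio_segment()] at `audio_rate_hz`) and
#'   `truth` (as in [gen_clickstream()]).
#' @export
gen_audio <- function(scen) {
  g <- gen_truth(scen)
  fs <- scen$audio_rate_hz
  n <- round(scen$duration_s * fs)
  x <- if (scen$noise_rms > 0) {
    with_seed(scen$seed + 900007, rnorm(n, 0, scen$noise_rms))
  } else {
    numeric(n)
  }
  pings <- g$pings
  if (!is.null(g$echoes)) {
    pings <- rbind(pings, g$echoes)
  }
  dur <- scen$ping_duration_s
  nb <- round(dur * fs)
  ramp_n <- round(0.0005 * fs)
  env <- rep(1, nb)
  if (ramp_n > 0 && 2 * ramp_n <= nb) {
    ramp <- 0.5 - 0.5 * cos(pi * seq_len(ramp_n) / ramp_n)
    env[seq_len(ramp_n)] <- ramp
    env[(nb - ramp_n + 1):nb] <- rev(ramp)
  }
  for (k in seq_len(nrow(pings))) {
    amp <- min(1, 10^((pings$rl_db[k] - scen$full_scale_db) / 20))
    i0 <- round(pings$time_s[k] * fs - nb / 2) + 1L
    idx <- i0:(i0 + nb - 1L)
    ok <- idx >= 1L & idx <= n
    if (!any(ok)) next
    tt <- (seq_len(nb) - 1) / fs
    burst <- amp * env * sin(2 * pi * 69000 * tt)
    x[idx[ok]] <- x[idx[ok]] + burst[ok]
  }
  list(audio = audio_segment(pmax(-1, pmin(1, x)), fs),
       truth = g$truth)
}
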