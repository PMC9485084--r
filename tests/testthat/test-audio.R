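# Build a test waveform with tone bursts of `dur` seconds starting at the
# given times (raised-cosine ramps), plus optional white noise.
burst_signal <- function(starts, fs = 384000, dur = 0.005, freq = 69000,
                         amp = 0.5, total = max(starts) + 0.1,
                         noise_sd = 0) {
  n <- round(total * fs)
  x <- if (noise_sd > 0) rnorm(n, 0, noise_sd) else numeric(n)
  nb <- round(dur * fs)
  nr <- round(0.0005 * fs)
  env <- rep(1, nb)
  ramp <- 0.5 - 0.5 * cos(pi * seq_len(nr) / nr)
  env[seq_len(nr)] <- ramp
  env[(nb - nr + 1):nb] <- rev(ramp)
  tt <- (seq_len(nb) - 1) / fs
  for (s in starts) {
    i0 <- round(s * fs) + 1L
    x[i0:(i0 + nb - 1L)] <- x[i0:(i0 + nb - 1L)] +
      amp * env * sin(2 * pi * freq * tt)
  }
  audio_segment(x, fs)
}

test_that("audio below 140 kS/s is refused, faster rates pass", {
  expect_true(validate_audio(audio_segment(numeric(10), 384000)))
  expect_true(validate_audio(audio_segment(numeric(10), 144000)))
  expect_error(validate_audio(audio_segment(numeric(10), 96000)), "140000")
})

test_that("a single high-SNR burst is detected at its envelope center", {
  set.seed(1)
  seg <- burst_signal(1.0, noise_sd = 0.01)  # SNR well above 10
  cs <- detect_pings(seg)
  expect_equal(cs$source, "audio")
  expect_equal(nrow(cs$events), 1)
  # 5 ms burst starting at 1.0 s: envelope center at 1.0025 s
  expect_lt(abs(cs$events$time_s - 1.0025), 5e-4)
  expect_lt(abs(cs$events$freq_khz - 69), 0.5)
  expect_gt(cs$events$n_cycles, 200)  # ~345 carrier cycles in 5 ms
})

test_that("peak-time error stays below 0.5 ms across noise realizations", {
  for (seed in 1:10) {
    set.seed(seed)
    seg <- burst_signal(0.5, amp = 0.4, noise_sd = 0.04)  # SNR = 10
    cs <- detect_pings(seg)
    expect_equal(nrow(cs$events), 1)
    expect_lt(abs(cs$events$time_s - 0.5025), 5e-4)
  }
})

test_that("noise alone stays below an absolute threshold; silence is empty", {
  set.seed(2)
  noise <- audio_segment(rnorm(384000 / 2, 0, 0.01), 384000)
  cfg <- audio_detector_config(envelope_threshold = 0.2,
                               threshold_mode = "absolute")
  expect_equal(nrow(detect_pings(noise, cfg)$events), 0)
  expect_equal(nrow(detect_pings(audio_segment(numeric(1000), 384000))$events),
               0)
})

test_that("two bursts a sync interval apart measure 0.280 s within 1 ms", {
  set.seed(3)
  seg <- burst_signal(c(1.0, 1.280), noise_sd = 0.005)
  cs <- detect_pings(seg)
  expect_equal(nrow(cs$events), 2)
  expect_lt(abs(diff(cs$events$time_s) - 0.280), 1e-3)
})

test_that("the band-pass rejects tones an octave off-center by >= 40 dB", {
  fs <- 384000
  t <- (0:(fs / 10)) / fs
  in_band <- podtag:::bandpass_carrier(sin(2 * pi * 69000 * t), fs, 69, 3)
  off_band <- podtag:::bandpass_carrier(sin(2 * pi * 34500 * t), fs, 69, 3)
  # compare mid-signal RMS to avoid filter edge transients
  mid <- seq(round(length(t) * 0.25), round(length(t) * 0.75))
  rej_db <- 20 * log10(sqrt(mean(in_band[mid]^2)) /
                         sqrt(mean(off_band[mid]^2)))
  expect_gt(rej_db, 40)
})

test_that("ping templates are extracted, normalized, and re-detectable", {
  set.seed(4)
  seg <- burst_signal(1.0, noise_sd = 0.002)
  cs <- detect_pings(seg)
  tpl <- extract_ping_template(seg, cs$events$time_s, 0.010)
  expect_equal(max(abs(tpl$samples)), 0.9, tolerance = 1e-9)
  expect_equal(round(length(tpl$samples) / tpl$sample_rate_hz, 3), 0.010)
  re <- detect_pings(tpl)
  expect_equal(nrow(re$events), 1)
  expect_error(extract_ping_template(seg, audio_duration(seg), 0.010),
               "outside")
  expect_error(extract_ping_template(seg, 0.001, 0.010), "outside")
})

test_that("fractional detector thresholds outside (0,1) are rejected", {
  expect_error(audio_detector_config(envelope_threshold = 1.2), "0, 1")
  expect_silent(audio_detector_config(envelope_threshold = 1.2,
                                      threshold_mode = "absolute"))
})
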