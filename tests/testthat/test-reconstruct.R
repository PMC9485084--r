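test_that("default reconstruction matches the 5 s / 384 kHz / 1000 ms layout", {
  tpl <- make_ping_template()
  iv <- c(0.280, rep(0.455, 6))
  wav <- reconstruct_packet_audio(tpl, iv)
  expect_equal(wav$sample_rate_hz, 384000)
  expect_equal(length(wav$samples), 5 * 384000)
  cs <- detect_pings(wav)
  expect_equal(nrow(cs$events), 8)
  # first ping peak at T = 1000 ms, within one sample
  expect_lte(abs(cs$events$time_s[1] - 1.0), 1 / 384000)
  expect_lte(max(abs(wav$samples)), 0.9 + 1e-9)  # silence baseline: no clip
})

test_that("duration extends beyond 5 s only when the packet needs it", {
  tpl <- make_ping_template()
  iv_long <- c(0.280, rep(0.511, 6))  # sums to 3.346 s
  wav <- reconstruct_packet_audio(tpl, iv_long)
  expect_equal(length(wav$samples) / wav$sample_rate_hz, 5.0)
  cfg <- reconstruction_config(lead_in_s = 2.0)
  wav2 <- reconstruct_packet_audio(tpl, iv_long, cfg)
  expected <- 2.0 + sum(iv_long) + audio_duration(tpl) + 0.5
  expect_equal(length(wav2$samples) / wav2$sample_rate_hz, expected,
               tolerance = 1e-6)
})

test_that("reconstruction followed by detection returns the intervals", {
  tpl <- make_ping_template()
  set.seed(5)
  for (k in 1:5) {
    iv <- encode_tag(sample(0:32767, 1))
    wav <- reconstruct_packet_audio(tpl, iv)
    got <- diff(detect_pings(wav)$events$time_s)
    expect_equal(length(got), 7)
    expect_lt(max(abs(got - iv)), 1e-3)
  }
})

test_that("templates resampled from another rate still round-trip", {
  tpl <- make_ping_template(sample_rate_hz = 192000)
  iv <- encode_tag(12345)
  wav <- reconstruct_packet_audio(tpl, iv)
  expect_equal(wav$sample_rate_hz, 384000)
  got <- diff(detect_pings(wav)$events$time_s)
  expect_lt(max(abs(got - iv)), 1e-3)
})

test_that("overlapping or empty templates are refused", {
  long_tpl <- make_ping_template(duration_s = 0.3)
  expect_error(reconstruct_packet_audio(long_tpl, encode_tag(0)), "overlap")
  empty <- audio_segment(numeric(0), 384000)
  expect_error(reconstruct_packet_audio(empty, encode_tag(0)), "empty")
  expect_error(reconstruct_packet_audio(make_ping_template(),
                                        rep(0.455, 6)), "7 positive")
})

test_that("batch reconstruction names files by first ping time", {
  tpl <- make_ping_template()
  pks <- list(code_packet(1 + cumsum(c(0, encode_tag(1))), score = 100),
              code_packet(11 + cumsum(c(0, encode_tag(2))), score = 100),
              code_packet(21.5 + cumsum(c(0, encode_tag(3))), score = 100))
  out <- withr::local_tempdir()
  paths <- batch_reconstruct(pks, tpl, out_dir = out)
  expect_length(paths, 3)
  expect_equal(basename(paths[1]), "packet_1.000.wav")
  expect_true(all(file.exists(paths)))
  expect_length(batch_reconstruct(list(), tpl, out_dir = out), 0)
  # collision rule: identical first-ping times get suffixed names
  twins <- list(pks[[1]], pks[[1]])
  paths2 <- batch_reconstruct(twins, tpl, out_dir = withr::local_tempdir())
  expect_equal(basename(paths2),
               c("packet_1.000.wav", "packet_1.000_1.wav"))
})

test_that("WAV files round-trip through the PCM16 reader/writer", {
  seg <- make_ping_template(192000)
  f <- withr::local_tempfile(fileext = ".wav")
  write_wav(seg, f)
  back <- read_wav(f)
  expect_equal(back$sample_rate_hz, 192000)
  expect_equal(length(back$samples), length(seg$samples))
  expect_lt(max(abs(back$samples - seg$samples)), 1 / 32767)
})
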