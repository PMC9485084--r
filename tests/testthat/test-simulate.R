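test_that("transmission loss follows the spreading + absorption form", {
  expect_equal(transmission_loss(1), 0.025)
  expect_equal(transmission_loss(100), 42.5)
  # independent closed-form evaluation at 500 m
  expect_equal(transmission_loss(500), 20 * log10(500) + 0.025 * 500)
  expect_equal(transmission_loss(500), 66.479, tolerance = 1e-3)
  expect_error(transmission_loss(0.5), ">= 1")
  r <- seq(1, 1000, by = 7)
  expect_true(all(diff(transmission_loss(r)) > 0))
})

test_that("a clean 60 s scenario transmits the counted number of packets", {
  scen <- scenario(tag_id = 42, duration_s = 60, transmit_period_s = 10,
                   start_phase_s = 2, clutter_rate_hz = 0, seed = 9)
  sim <- gen_clickstream(scen)
  expect_equal(nrow(sim$truth), 6)  # floor((60-2)/10) + 1
  expect_equal(nrow(sim$stream$events), 6 * 8)
  expect_true(all(sim$truth$complete))
  expect_equal(unique(sim$truth$tag_id), 42)
  # logged frequencies stay inside the tag band
  expect_true(all(sim$stream$events$freq_khz >= 69 - 0.25 &
                    sim$stream$events$freq_khz <= 69 + 0.25))
})

test_that("the truth-log count formula holds under random phase", {
  for (seed in 1:10) {
    scen <- scenario(tag_id = 1, duration_s = 47, transmit_period_s = 10,
                     seed = seed)
    sim <- gen_clickstream(scen)
    phase <- sim$truth$packet_time_s[1]
    expect_equal(nrow(sim$truth), floor((47 - phase) / 10) + 1)
  }
})

test_that("identical seeds give bit-identical streams and audio", {
  scen <- scenario(tag_id = 7, duration_s = 20, clutter_rate_hz = 1,
                   fading_sd_db = 2, noise_rms = 0.01,
                   audio_rate_hz = 144000, seed = 33)
  expect_identical(gen_clickstream(scen), gen_clickstream(scen))
  expect_identical(gen_audio(scen)$audio$samples,
                   gen_audio(scen)$audio$samples)
  scen2 <- scen; scen2$seed <- 34L
  expect_false(identical(gen_clickstream(scen)$stream$events,
                         gen_clickstream(scen2)$stream$events))
})

test_that("beyond the detection range only clutter is logged", {
  scen <- scenario(tag_id = 5, range_m = 5000, duration_s = 60,
                   clutter_rate_hz = 0.5, detection_threshold_db = 90,
                   seed = 4)
  sim <- gen_clickstream(scen)
  # at 5 km the received level is ~140 dB below source: all tag pings gone
  expect_true(all(sim$stream$events$n_cycles < 300 |
                    sim$stream$events$freq_khz != 69))
  pks <- find_packets(sim$stream)
  expect_length(pks, 0)
})

test_that("multipath echoes are logged but do not break decoding", {
  echoes <- data.frame(delay_s = c(0.003, 0.006), rel_db = c(-6, -12))
  scen <- scenario(tag_id = 31000, duration_s = 30, start_phase_s = 1,
                   multipath_echoes = echoes, seed = 12)
  sim <- gen_clickstream(scen)
  expect_gt(nrow(sim$stream$events), 3 * 8)  # echoes present
  pks <- find_packets(sim$stream)
  expect_gte(length(pks), 1)
  expect_gt(pks[[1]]$n_stray, 0)
  expect_lt(pks[[1]]$score, 100)
  expect_equal(decode_intervals(pks[[1]]$intervals_s)$tag_id, 31000L)
})

test_that("generated audio packets survive detection and decoding", {
  scen <- scenario(tag_id = 2048, duration_s = 5, start_phase_s = 0.5,
                   audio_rate_hz = 192000, range_m = 20, noise_rms = 0.002,
                   seed = 21)
  ga <- gen_audio(scen)
  cs <- detect_pings(ga$audio)
  expect_equal(nrow(cs$events), 8)
  pks <- find_packets(cs)
  expect_length(pks, 1)
  expect_equal(decode_intervals(pks[[1]]$intervals_s)$tag_id, 2048L)
  # a scenario whose first transmission falls after the end is pure noise
  quiet <- scenario(tag_id = 2048, duration_s = 5, start_phase_s = 9,
                    audio_rate_hz = 192000, noise_rms = 0.002, seed = 21)
  gq <- gen_audio(quiet)
  expect_equal(nrow(gq$truth), 0)
  expect_length(find_packets(detect_pings(
    gq$audio, audio_detector_config(envelope_threshold = 0.05,
                                    threshold_mode = "absolute"))), 0)
})

test_that("clean end-to-end decoding recovers the transmitted identity", {
  set.seed(2024)
  ids <- sample(0:32767, 200)
  for (k in seq_along(ids)) {
    scen <- scenario(tag_id = ids[k], duration_s = 15, start_phase_s = 0.5,
                     seed = 3000 + k)
    sim <- gen_clickstream(scen)
    pks <- find_packets(sim$stream)
    expect_gte(length(pks), 1)
    expect_equal(decode_intervals(pks[[1]]$intervals_s)$tag_id, ids[k])
  }
})

test_that("scenario validation catches impossible setups", {
  expect_error(scenario(tag_id = 1, range_m = 0.5), "range_m")
  expect_error(scenario(tag_id = 1, transmit_period_s = 3), "packet span")
  expect_error(scenario(tag_id = 1, audio_rate_hz = 96000), "140000")
  expect_error(scenario(tag_id = 40000), "tag_id")
})
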