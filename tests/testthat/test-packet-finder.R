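mk_event <- function(t, f = 70, cyc = 40, a = 1) {
  data.frame(time_s = t, freq_khz = f, n_cycles = cyc, amplitude = a)
}

test_that("band/cycle filter boundaries are inclusive as specified", {
  ev <- rbind(mk_event(1, f = 70.0, cyc = 5),    # kept: 5-cycle floor
              mk_event(2, f = 68.9, cyc = 40),   # out of band (low)
              mk_event(3, f = 70.0, cyc = 4),    # below cycle floor
              mk_event(4, f = 69.0, cyc = 40),   # kept: lower edge
              mk_event(5, f = 72.0, cyc = 40),   # kept: upper edge
              mk_event(6, f = 72.1, cyc = 40))   # out of band (high)
  out <- band_cycle_filter(click_stream(ev, "synthetic"))
  expect_equal(out$events$time_s, c(1, 4, 5))
})

test_that("filter output is a subsequence and the filter is idempotent", {
  for (seed in 1:20) {
    cs <- random_finder_stream(seed)
    f1 <- band_cycle_filter(cs)
    expect_true(all(f1$events$time_s %in% cs$events$time_s))
    expect_lte(nrow(f1$events), nrow(cs$events))
    expect_identical(band_cycle_filter(f1)$events, f1$events)
  }
})

test_that("multipath classification separates echoes, strays and candidates", {
  cfg <- finder_config()
  acc <- mk_event(1.0, a = 1)
  expect_equal(classify_multipath(acc, mk_event(1.004, a = 0.5), cfg),
               "multipath")
  expect_equal(classify_multipath(acc, mk_event(1.004, a = 1.5), cfg),
               "stray")
  expect_equal(classify_multipath(acc, mk_event(1.1, a = 0.5), cfg),
               "stray")
  expect_equal(classify_multipath(acc, mk_event(1.455, a = 1), cfg),
               "primary_candidate")
  expect_error(classify_multipath(acc, mk_event(0.9), cfg), "later")
})

test_that("packet score follows the linear penalty formula", {
  cfg <- finder_config()
  expect_equal(score_packet(rep(1, 8), 0, cfg), 100)
  expect_equal(score_packet(rep(1, 8), 2, cfg), 80)
  # amplitude spread case, checked against an independent evaluation of the
  # population coefficient of variation
  a <- c(rep(1, 7), 2)
  cv <- sqrt(sum((a - mean(a))^2) / length(a)) / mean(a)
  expect_equal(score_packet(a, 0, cfg), 100 - 100 * cv)
  expect_equal(score_packet(a, 0, cfg), 70.6, tolerance = 0.01)
  expect_equal(score_packet(rep(1, 8), 50, cfg), 0)  # clamped at zero
  expect_error(score_packet(c(rep(1, 7), -1), 0, cfg), "positive")
})

test_that("score never rises with extra strays or wider amplitude spread", {
  cfg <- finder_config()
  for (seed in 1:20) {
    set.seed(seed)
    a <- exp(rnorm(8, 0, 0.3))
    ns <- sample(0:3, 1)
    expect_lte(score_packet(a, ns + 1, cfg), score_packet(a, ns, cfg))
    # mean-preserving spread: push amplitudes away from their mean
    spread <- mean(a) + (a - mean(a)) * 1.5
    if (all(spread > 0)) {
      expect_lte(score_packet(spread, ns, cfg), score_packet(a, ns, cfg))
    }
  }
})

test_that("a clean 8-ping stream yields one perfect packet", {
  t <- c(0, 0.280, 0.735, 1.190, 1.645, 2.100, 2.555, 3.010)
  cs <- click_stream(mk_event(t, f = 69), "synthetic")
  pks <- find_packets(cs)
  expect_length(pks, 1)
  expect_equal(pks[[1]]$intervals_s, c(0.280, rep(0.455, 6)))
  expect_equal(pks[[1]]$score, 100)
  expect_equal(pks[[1]]$n_stray, 0)
})

test_that("a truncated packet (sync pair + 5 pings) is rejected", {
  t <- c(0, 0.280, 0.735, 1.190, 1.645, 2.100, 2.555)
  pks <- find_packets(click_stream(mk_event(t, f = 69), "synthetic"))
  expect_length(pks, 0)
})

test_that("a weak echo inside the packet is tolerated and penalized", {
  t <- c(0, 0.280, 0.735, 1.190, 1.645, 2.100, 2.555, 3.010)
  ev <- rbind(mk_event(t, f = 69), mk_event(0.284, f = 69, a = 0.3))
  pks <- find_packets(click_stream(ev, "synthetic"))
  expect_length(pks, 1)
  expect_equal(pks[[1]]$ping_times_s, t)
  expect_equal(pks[[1]]$n_stray, 1)
  expect_equal(pks[[1]]$score, 90)
})

test_that("every returned packet satisfies the packet invariants", {
  cfg <- finder_config()
  for (seed in 1:60) {
    for (p in find_packets(random_finder_stream(seed), cfg)) {
      expect_length(p$ping_times_s, 8)
      expect_equal(p$intervals_s, diff(p$ping_times_s))
      expect_lte(abs(p$intervals_s[1] - cfg$sync_interval_s),
                 cfg$sync_tol_s + 1e-9)
      span <- max(p$ping_times_s) - min(p$ping_times_s)
      expect_gte(span, cfg$packet_len_min_s - 1e-9)
      expect_lte(span, cfg$packet_len_max_s + 1e-9)
      expect_gte(p$score, 0)
      expect_lte(p$score, 100)
    }
  }
})

test_that("config invariants are enforced", {
  expect_error(finder_config(band_lo_khz = 73), "band_lo")
  expect_error(finder_config(sync_tol_s = 0), "sync_tol")
  expect_error(finder_config(n_pings_per_packet = 7), "sync pair")
})
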