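# Fixture builders shared across the suite. Everything is generated in code;
# no stored data.

# A noise-free click stream carrying one packet for `tag_id`, all pings at
# 69 kHz / 345 cycles / equal amplitude, first ping at `t0`.
clean_packet_stream <- function(tag_id = 668, t0 = 0.5, amplitude = 1,
                                map = default_codemap()) {
  times <- t0 + cumsum(c(0, encode_tag(tag_id, map)))
  click_stream(data.frame(time_s = times, freq_khz = 69, n_cycles = 345,
                          amplitude = amplitude),
               source = "synthetic")
}

# Seeded random stream of <= 30 events for the finder-vs-oracle comparison:
# usually a jittered (sometimes broken) packet plus clutter and echo-like
# events, occasionally pure clutter.
random_finder_stream <- function(seed) {
  set.seed(seed)
  ev <- NULL
  if (runif(1) < 0.8) {
    iv <- encode_tag(sample(0:32767, 1))
    jit_sd <- sample(c(0.0005, 0.002, 0.02), 1)
    times <- runif(1, 0, 1.5) + cumsum(c(0, iv + rnorm(7, 0, jit_sd)))
    ev <- data.frame(time_s = times, freq_khz = 69.5, n_cycles = 40,
                     amplitude = exp(rnorm(8, 0, 0.2)))
    if (runif(1) < 0.4) {  # echo-like copies shortly after real pings
      k <- sample(8, sample(1:2, 1))
      ev <- rbind(ev, data.frame(time_s = ev$time_s[k] + runif(length(k),
                                                              0.001, 0.012),
                                 freq_khz = 69.5, n_cycles = 40,
                                 amplitude = ev$amplitude[k] *
                                   runif(length(k), 0.2, 1.3)))
    }
  }
  n_extra <- sample(0:10, 1)
  if (n_extra) {
    ev <- rbind(ev, data.frame(
      time_s = runif(n_extra, 0, 6),
      freq_khz = sample(c(69.5, 71, 80), n_extra, replace = TRUE,
                        prob = c(0.6, 0.2, 0.2)),
      n_cycles = sample(c(40, 3), n_extra, replace = TRUE,
                        prob = c(0.85, 0.15)),
      amplitude = exp(rnorm(n_extra, -0.5, 0.5))))
  }
  if (is.null(ev) || !nrow(ev)) {
    ev <- data.frame(time_s = 0.1, freq_khz = 69.5, n_cycles = 40,
                     amplitude = 1)
  }
  ev$time_s <- ev$time_s - min(ev$time_s)  # keep times non-negative
  click_stream(ev, source = "synthetic")
}
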