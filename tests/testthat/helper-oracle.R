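# Independent brute-force packet search: enumerate every admissible 8-event
# subsequence (sync window, data-interval windows, packet-length window),
# keep the lexicographically smallest completion per sync anchor, then apply
# the same earliest-anchor-wins span suppression the finder documents. Used
# only as an oracle on small streams.
oracle_find_packets <- function(stream, cfg = finder_config()) {
  stream <- band_cycle_filter(stream, cfg)
  t <- stream$events$time_s
  a <- stream$events$amplitude
  n <- length(t)
  eps <- 1e-9
  complete <- list()

  grow <- function(idx) {
    if (length(idx) == cfg$n_pings_per_packet) {
      span <- t[idx[length(idx)]] - t[idx[1]]
      if (span >= cfg$packet_len_min_s - eps &&
          span <= cfg$packet_len_max_s + eps) {
        complete[[length(complete) + 1L]] <<- idx
      }
      return(invisible(NULL))
    }
    last <- idx[length(idx)]
    for (m in seq_len(n)) {
      if (m <= last) next
      g <- t[m] - t[last]
      if (g >= cfg$data_interval_min_s - eps &&
          g <= cfg$data_interval_max_s + eps) {
        grow(c(idx, m))
      }
    }
  }

  if (n >= cfg$n_pings_per_packet) {
    for (i in seq_len(n - 1)) {
      for (j in seq_len(n)) {
        if (j > i && abs(t[j] - t[i] - cfg$sync_interval_s) <=
            cfg$sync_tol_s + eps) {
          grow(c(i, j))
        }
      }
    }
  }
  if (!length(complete)) return(list())

  # lexicographically smallest completion per anchor pair
  anchors <- vapply(complete, function(x) paste(x[1], x[2]), character(1))
  picked <- lapply(split(complete, anchors), function(grp) {
    best <- grp[[1]]
    for (x in grp[-1]) {
      d <- which(x != best)
      if (length(d) && x[d[1]] < best[d[1]]) best <- x
    }
    best
  })

  pack <- lapply(picked, function(idx) {
    in_span <- which(t >= t[idx[1]] - eps & t <= t[idx[length(idx)]] + eps)
    ns <- length(setdiff(in_span, idx))
    code_packet(t[idx], score = score_packet(a[idx], ns, cfg), n_stray = ns)
  })
  t1 <- vapply(pack, function(p) p$first_ping_time_s, numeric(1))
  sc <- vapply(pack, function(p) p$score, numeric(1))
  pack <- pack[order(t1, -sc)]

  out <- list()
  spans <- NULL
  for (p in pack) {
    t0 <- p$first_ping_time_s
    if (!is.null(spans) &&
        any(t0 >= spans[, 1] - eps & t0 <= spans[, 2] + eps)) next
    out[[length(out) + 1L]] <- p
    spans <- rbind(spans, c(t0, max(p$ping_times_s)))
  }
  out
}
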