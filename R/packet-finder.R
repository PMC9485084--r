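#' Packet-finder configuration
#'
#' Parameters of the click-stream route: the band/cycle pre-filter, the sync
#' anchored packet search, multipath tolerance and quality scoring. Defaults
#' follow the timing profile of 69 kHz coded fish tags: a fixed 0.280 s gap
#' between the first and second ping, at least 6 further pings, 8 pings total
#' spanning 3–3.5 s, and a logger-side pre-filter keeping only 69–72 kHz pings
#' of at least 5 carrier cycles.
#'
#' @param band_lo_khz,band_hi_khz inclusive frequency band for candidate tag
#'   pings (kHz).
#' @param min_cycles minimum ping duration in carrier cycles (inclusive).
#' @param sync_interval_s nominal sync (first inter-ping) interval, seconds.
#' @param sync_tol_s tolerance around the sync interval when anchoring.
#' @param min_subsequent_pings pings required after the sync pair.
#' @param n_pings_per_packet pings per packet (sync pair + data pings).
#' @param packet_len_min_s,packet_len_max_s admissible first-to-last ping span.
#' @param data_interval_min_s,data_interval_max_s admissible data inter-ping
#'   interval window, seconds.
#' @param multipath_window_s a weaker transient this close after an accepted
#'   ping is treated as a multipath echo of it.
#' @param stray_penalty score penalty per stray/multipath ping in the packet
#'   span.
#' @param amp_cv_penalty_scale score penalty per unit coefficient of variation
#'   of the 8 ping amplitudes.
#' @return A classed list (`finder_config`).
#' @export
finder_config <- function(band_lo_khz = 69.0, band_hi_khz = 72.0,
                          min_cycles = 5, sync_interval_s = 0.280,
                          sync_tol_s = 0.005, min_subsequent_pings = 6,
                          n_pings_per_packet = 8,
                          packet_len_min_s = 3.0, packet_len_max_s = 3.5,
                          data_interval_min_s = 0.40,
                          data_interval_max_s = 0.60,
                          multipath_window_s = 0.008,
                          stray_penalty = 10.0,
                          amp_cv_penalty_scale = 100.0) {
  cfg <- list(band_lo_khz = band_lo_khz, band_hi_khz = band_hi_khz,
              min_cycles = min_cycles, sync_interval_s = sync_interval_s,
              sync_tol_s = sync_tol_s,
              min_subsequent_pings = min_subsequent_pings,
              n_pings_per_packet = n_pings_per_packet,
              packet_len_min_s = packet_len_min_s,
              packet_len_max_s = packet_len_max_s,
              data_interval_min_s = data_interval_min_s,
              data_interval_max_s = data_interval_max_s,
              multipath_window_s = multipath_window_s,
              stray_penalty = stray_penalty,
              amp_cv_penalty_scale = amp_cv_penalty_scale)
  if (cfg$band_lo_khz >= cfg$band_hi_khz) {
    stop("band_lo_khz must be < band_hi_khz", call. = FALSE)
  }
  if (cfg$sync_tol_s <= 0) stop("sync_tol_s must be > 0", call. = FALSE)
  if (cfg$packet_len_min_s >= cfg$packet_len_max_s) {
    stop("packet_len_min_s must be < packet_len_max_s", call. = FALSE)
  }
  if (cfg$data_interval_min_s >= cfg$data_interval_max_s) {
    stop("data_interval_min_s must be < data_interval_max_s", call. = FALSE)
  }
  if (cfg$n_pings_per_packet < 2 + cfg$min_subsequent_pings) {
    stop("n_pings_per_packet must cover the sync pair plus ",
         "min_subsequent_pings data pings", call. = FALSE)
  }
  structure(cfg, class = "finder_config")
}

#' Construct a code packet
#'
#' A candidate tag transmission: 8 ascending ping times whose consecutive
#' differences are the 7 PPM intervals, plus a 0–100 quality score.
#'
#' @param ping_times_s ascending ping times (seconds).
#' @param score quality score in \[0, 100\].
#' @param n_stray stray/multipath transients counted inside the packet span
#'   (NA when unknown, e.g. on re-read from a text export).
#' @param amp_cv coefficient of variation of the ping amplitudes (NA when
#'   unknown).
#' @return Object of class `code_packet` with fields `ping_times_s`,
#'   `intervals_s`, `first_ping_time_s`, `score`, `n_stray`, `amp_cv`.
#' @export
code_packet <- function(ping_times_s, score, n_stray = NA_real_,
                        amp_cv = NA_real_) {
  ping_times_s <- as.numeric(ping_times_s)
  if (is.unsorted(ping_times_s, strictly = TRUE)) {
    stop("ping_times_s must be strictly ascending", call. = FALSE)
  }
  if (!is.na(score) && (score < 0 || score > 100)) {
    stop("score must lie in [0, 100]", call. = FALSE)
  }
  structure(list(ping_times_s = ping_times_s,
                 intervals_s = diff(ping_times_s),
                 first_ping_time_s = ping_times_s[1],
                 score = score, n_stray = n_stray, amp_cv = amp_cv),
            class = "code_packet")
}

#' @export
print.code_packet <- function(x, ...) {
  cat(sprintf("<code_packet t0=%.6f s, intervals [%s] s, score %.1f>\n",
              x$first_ping_time_s,
              paste(sprintf("%.3f", x$intervals_s), collapse = ", "),
              x$score))
  invisible(x)
}

#' Band and cycle-count pre-filter
#'
#' Keeps only events inside the tag frequency band (inclusive on both edges)
#' with at least the minimum duration in carrier cycles — the logger-side
#' filter that removes all except 69–72 kHz pings of >= 5 cycles under the
#' defaults. Idempotent; order preserving.
#'
#' @param stream a [click_stream()].
#' @param cfg a [finder_config()].
#' @return The filtered [click_stream()] (possibly empty), same `duration_s`.
#' @export
band_cycle_filter <- function(stream, cfg = finder_config()) {
  stopifnot(inherits(stream, "click_stream"))
  ev <- stream$events
  keep <- ev$freq_khz >= cfg$band_lo_khz & ev$freq_khz <= cfg$band_hi_khz &
    ev$n_cycles >= cfg$min_cycles
  out <- stream
  out$events <- ev[keep, , drop = FALSE]
  rownames(out$events) <- NULL
  out
}

#' Classify a transient relative to the last accepted packet ping
#'
#' A candidate arriving within `multipath_window_s` of an accepted ping and
#' weaker than it is a multipath echo; a candidate closer than the minimum
#' data interval but not an echo is a stray; anything else is a primary
#' candidate for the next packet position.
#'
#' @param accepted_ping,candidate single-row data.frames (or lists) with
#'   `time_s` and `amplitude`; `candidate` must be later.
#' @param cfg a [finder_config()].
#' @return `"multipath"`, `"stray"` or `"primary_candidate"`.
#' @export
classify_multipath <- function(accepted_ping, candidate,
                               cfg = finder_config()) {
  gap <- candidate$time_s - accepted_ping$time_s
  if (gap <= 0) stop("candidate must be later than the accepted ping",
                     call. = FALSE)
  if (gap <= cfg$multipath_window_s &&
      candidate$amplitude < accepted_ping$amplitude) {
    return("multipath")
  }
  if (gap < cfg$data_interval_min_s) return("stray")
  "primary_candidate"
}

#' Score a candidate packet
#'
#' Linear quality score: starts at 100, loses `stray_penalty` per stray or
#' multipath transient inside the packet span and `amp_cv_penalty_scale` times
#' the coefficient of variation (population SD / mean) of the 8 ping
#' amplitudes, clamped to \[0, 100\]. High for clean data; falls with clutter,
#' echoes, or widely varying ping amplitudes.
#'
#' @param pings numeric amplitudes of the packet pings, or a data.frame with
#'   an `amplitude` column.
#' @param n_stray count of stray/multipath transients within the packet span.
#' @param cfg a [finder_config()].
#' @return score in \[0, 100\].
#' @export
score_packet <- function(pings, n_stray, cfg = finder_config()) {
  amps <- if (is.data.frame(pings)) pings$amplitude else as.numeric(pings)
  if (any(amps <= 0)) stop("ping amplitudes must be positive", call. = FALSE)
  m <- mean(amps)
  if (m <= 0) stop("mean ping amplitude must be positive", call. = FALSE)
  cv <- sqrt(mean((amps - m)^2)) / m
  max(0, min(100, 100 - cfg$stray_penalty * n_stray -
                  cfg$amp_cv_penalty_scale * cv))
}

# Earliest-first depth-first extension from a sync anchor. Returns the
# lexicographically smallest admissible completion (indices into t) or NULL.
# Greedy earliest-candidate choice with backtracking: backtracking only fires
# when the locally earliest pick cannot complete a packet that another pick
# could, which keeps the search equivalent to exhaustive enumeration.
.extend_packet <- function(t, i1, accepted, cfg) {
  eps <- 1e-9
  if (length(accepted) == cfg$n_pings_per_packet) {
    span <- t[accepted[length(accepted)]] - t[i1]
    if (span >= cfg$packet_len_min_s - eps &&
        span <= cfg$packet_len_max_s + eps) {
      return(accepted)
    }
    return(NULL)
  }
  last <- accepted[length(accepted)]
  gaps <- t - t[last]
  cand <- which(gaps >= cfg$data_interval_min_s - eps &
                  gaps <= cfg$data_interval_max_s + eps &
                  t - t[i1] <= cfg$packet_len_max_s + eps)
  for (m in cand) {
    res <- .extend_packet(t, i1, c(accepted, m), cfg)
    if (!is.null(res)) return(res)
  }
  NULL
}

#' Search a click stream for code packets
#'
#' Applies [band_cycle_filter()] defensively, then anchors on every ping pair
#' whose gap lies within `sync_tol_s` of the sync interval and extends each
#' anchor with the earliest subsequent admissible ping (gap inside the data
#' interval window; multipath echoes and strays skipped) until a full packet
#' of `n_pings_per_packet` pings is accepted, subject to the 3–3.5 s packet
#' length window. Each packet is scored with [score_packet()], counting every
#' non-packet transient inside the packet span as a stray. Anchors falling
#' inside an already accepted packet's span are suppressed
#' (earliest-anchor-wins; ties broken by higher score).
#'
#' @param stream a [click_stream()] (pre-filtering is optional; the filter is
#'   idempotent).
#' @param cfg a [finder_config()].
#' @return List of [code_packet()] objects in ascending first-ping order
#'   (empty list when no packet is found).
#' @export
find_packets <- function(stream, cfg = finder_config()) {
  stream <- band_cycle_filter(stream, cfg)
  ev <- stream$events
  n <- nrow(ev)
  if (n < cfg$n_pings_per_packet) return(list())
  t <- ev$time_s
  a <- ev$amplitude
  eps <- 1e-9

  cand <- list()
  for (i in seq_len(n - 1L)) {
    gaps <- t - t[i]
    js <- which(gaps > 0 & abs(gaps - cfg$sync_interval_s) <=
                  cfg$sync_tol_s + eps)
    for (j in js) {
      idx <- .extend_packet(t, i, c(i, j), cfg)
      if (is.null(idx)) next
      span_lo <- t[idx[1]]
      span_hi <- t[idx[length(idx)]]
      in_span <- which(t >= span_lo & t <= span_hi)
      n_stray <- length(setdiff(in_span, idx))
      cand[[length(cand) + 1L]] <- code_packet(
        ping_times_s = t[idx],
        score = score_packet(a[idx], n_stray, cfg),
        n_stray = n_stray,
        amp_cv = {
          m <- mean(a[idx]); sqrt(mean((a[idx] - m)^2)) / m
        })
    }
  }
  if (!length(cand)) return(list())

  # earliest anchor wins; ties by higher score, then lexicographic ping times
  key <- vapply(cand, function(p) p$first_ping_time_s, numeric(1))
  sc <- vapply(cand, function(p) p$score, numeric(1))
  ord <- order(key, -sc)
  cand <- cand[ord]
  accepted <- list()
  spans <- matrix(numeric(), ncol = 2)
  for (p in cand) {
    t0 <- p$first_ping_time_s
    if (nrow(spans) &&
        any(t0 >= spans[, 1] - eps & t0 <= spans[, 2] + eps)) {
      next
    }
    accepted[[length(accepted) + 1L]] <- p
    spans <- rbind(spans, c(t0, p$ping_times_s[length(p$ping_times_s)]))
  }
  accepted
}
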