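#' Spike detector parameters
#'
#' Defaults for the interictal spike detector: amplitude threshold `k_amp`
#' times the rolling robust SD (1.4826 x MAD over `mad_window_s` blocks),
#' slope threshold `k_slope` times the robust scale of the first difference,
#' sharp-component half-amplitude duration within `[dur_min_ms, dur_max_ms]`,
#' and a per-channel refractory merge window.
#'
#' @param k_amp amplitude threshold multiplier.
#' @param k_slope slope threshold multiplier.
#' @param refractory_ms events closer than this on one channel are merged,
#'   keeping the larger.
#' @param dur_min_ms,dur_max_ms admissible sharp-component width (ms).
#' @param mad_window_s length of the rolling robust-scale window (s).
#' @param slope_window_ms window before the peak searched for a steep rise.
#' @return named list of parameters.
#' @export
spike_detect_params <- function(k_amp = 5, k_slope = 3, refractory_ms = 200,
                                dur_min_ms = 20, dur_max_ms = 200,
                                mad_window_s = 5, slope_window_ms = 40) {
  list(k_amp = k_amp, k_slope = k_slope, refractory_ms = refractory_ms,
       dur_min_ms = dur_min_ms, dur_max_ms = dur_max_ms,
       mad_window_s = mad_window_s, slope_window_ms = slope_window_ms)
}

# rolling robust SD: per-1-s-block MAD, median-smoothed over mad_window_s
rolling_robust_sd <- function(x, fs, window_s) {
  n <- length(x)
  bs <- max(1L, round(fs))
  nb <- ceiling(n / bs)
  blk <- vapply(seq_len(nb), function(b) {
    i0 <- (b - 1L) * bs + 1L
    mad(x[i0:min(b * bs, n)])
  }, numeric(1))
  half <- max(0L, floor(window_s / 2))
  sm <- vapply(seq_len(nb), function(b) {
    median(blk[max(1, b - half):min(nb, b + half)])
  }, numeric(1))
  rep(sm, each = bs)[seq_len(n)]
}

#' Detect interictal spikes on one channel
#'
#' A deterministic threshold detector: candidate events are local extrema of
#' the filtered signal whose absolute amplitude exceeds `k_amp` times the
#' rolling robust SD and that are preceded (within `slope_window_ms`) by a
#' first-difference exceeding `k_slope` times the robust slope scale; the
#' half-amplitude width of the sharp component must fall in
#' `[dur_min_ms, dur_max_ms]`. Events within the refractory window are merged
#' keeping the larger.
#'
#' @param x filtered, referenced single-channel signal (one analysis
#'   segment).
#' @param fs sampling rate (Hz).
#' @param params list from [spike_detect_params()].
#' @return data.frame with columns `peak_s` (seconds from segment start) and
#'   `amplitude` (signed, signal units).
#' @export
detect_spikes <- function(x, fs, params = spike_detect_params()) {
  if (!length(x)) stop("empty signal")
  if (all(x == x[1]))
    return(data.frame(peak_s = numeric(0), amplitude = numeric(0)))
  med <- median(x)
  if (abs(med) > 5 * mad(x) && mad(x) > 0)
    warning("signal looks DC-dominated; was it filtered?")
  n <- length(x)
  # mad() already includes the 1.4826 consistency constant
  thr <- params$k_amp * rolling_robust_sd(x, fs, params$mad_window_s)
  a <- abs(x)
  cand <- which(a[2:(n - 1)] >= a[1:(n - 2)] & a[2:(n - 1)] >= a[3:n]) + 1L
  cand <- cand[a[cand] > thr[cand]]
  if (!length(cand))
    return(data.frame(peak_s = numeric(0), amplitude = numeric(0)))
  dx <- abs(diff(x))
  slope_scale <- mad(dx)
  sw <- max(1L, round(params$slope_window_ms / 1000 * fs))
  keep <- logical(length(cand))
  dur_lo <- params$dur_min_ms / 1000 * fs
  dur_hi <- params$dur_max_ms / 1000 * fs
  for (k in seq_along(cand)) {
    i <- cand[k]
    i0 <- max(1L, i - sw)
    if (slope_scale > 0 &&
        max(dx[i0:max(i0, i - 1L)]) <= params$k_slope * slope_scale) next
    half <- a[i] / 2
    lo <- i; while (lo > 1L && a[lo - 1L] > half) lo <- lo - 1L
    hi <- i; while (hi < n && a[hi + 1L] > half) hi <- hi + 1L
    wid <- hi - lo + 1L
    keep[k] <- wid >= dur_lo && wid <= dur_hi
  }
  cand <- cand[keep]
  if (!length(cand))
    return(data.frame(peak_s = numeric(0), amplitude = numeric(0)))
  # refractory merge, keeping the larger event
  refr <- params$refractory_ms / 1000 * fs
  cand <- cand[order(cand)]
  out <- integer(0)
  for (i in cand) {
    if (length(out) && i - out[length(out)] <= refr) {
      if (a[i] > a[out[length(out)]]) out[length(out)] <- i
    } else out <- c(out, i)
  }
  data.frame(peak_s = (out - 1) / fs, amplitude = x[out])
}

#' Group spikes across channels into sequences
#'
#' Single-linkage temporal clustering: consecutive events (on any channel)
#' whose gap is at most `gap_ms` join the same sequence. Each event's latency
#' is its time minus the sequence's first-event time (ms); the first spike in
#' a sequence has latency exactly 0 ms.
#'
#' @param events data.frame with columns `channel` and `peak_s` (absolute
#'   seconds; events from different segments should not be pooled).
#' @param gap_ms linkage gap in milliseconds.
#' @return `events` ordered by time with added `sequence` (integer id) and
#'   `latency_ms` columns.
#' @export
group_sequences <- function(events, gap_ms = 100) {
  if (!nrow(events)) {
    events$sequence <- integer(0); events$latency_ms <- numeric(0)
    return(events)
  }
  events <- events[order(events$peak_s), , drop = FALSE]
  gaps <- diff(events$peak_s) * 1000
  seq_id <- cumsum(c(1L, as.integer(gaps > gap_ms)))
  first <- tapply(events$peak_s, seq_id, min)
  events$sequence <- seq_id
  events$latency_ms <-
    as.numeric((events$peak_s - first[as.character(seq_id)]) * 1000)
  rownames(events) <- NULL
  events
}

#' Per-channel spike rate (spikes/min)
#'
#' Rate over the non-excluded one-minute segments in the requested sleep
#' state: event count divided by the number of such segments. Channels are
#' taken from `channels`; a state with zero usable segments yields `NA`
#' (missing), never zero.
#'
#' @param events data.frame with columns `channel`, `segment` (row index into
#'   `segments`).
#' @param segments data.frame from [segment_record()] with stages assigned.
#' @param state `"N2N3"` or `"wake"`.
#' @param channels character vector of channel labels to report.
#' @return named numeric vector, spikes per minute (or `NA`).
#' @export
spike_rate <- function(events, segments, state, channels) {
  use <- which(!segments$excluded & segments$stage == state)
  if (!length(use))
    return(setNames(rep(NA_real_, length(channels)), channels))
  ev <- events[events$segment %in% use, , drop = FALSE]
  counts <- table(factor(ev$channel, levels = channels))
  setNames(as.numeric(counts) / length(use), channels)
}

#' Per-channel mean spike recruitment latency (ms)
#'
#' For each channel, the mean latency of its events across the sequences it
#' participates in. Channels with no spikes get `NA`.
#'
#' @param events sequence-annotated events from [group_sequences()].
#' @param channels channel labels to report.
#' @return named numeric vector of latencies in ms (or `NA`).
#' @export
recruitment_latency <- function(events, channels) {
  out <- setNames(rep(NA_real_, length(channels)), channels)
  if (!nrow(events)) return(out)
  m <- tapply(events$latency_ms, factor(events$channel, levels = channels),
              mean)
  out[names(m)] <- as.numeric(m)
  out
}
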