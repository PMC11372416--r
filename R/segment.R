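#' Draw random one-minute analysis segments
#'
#' Divides the record into consecutive 10-minute parent windows and draws one
#' 1-minute segment from each, with the start offset a uniformly distributed
#' integer number of seconds (0--540) inside the parent. Segments overlapping
#' any annotated seizure interval are marked excluded (they are not re-drawn).
#' A 12-hour record yields exactly 72 segments.
#'
#' @param recording an `ieeg_recording` (length >= 10 min).
#' @param seed integer seed for the segment draw (local RNG scope).
#' @param parent_s,segment_s parent window and segment lengths in seconds.
#' @return A `data.frame` with columns `parent` (1-based), `start` (s),
#'   `duration` (s), `stage` (`NA` until staged), `excluded`,
#'   `exclusion_reason`.
#' @export
segment_record <- function(recording, seed = 1, parent_s = 600,
                           segment_s = 60) {
  total_s <- recording_duration(recording)
  n_parents <- floor(total_s / parent_s)
  if (n_parents < 1) stop("record shorter than one parent window")
  offsets <- with_seed(seed,
    sample.int(parent_s - segment_s + 1L, n_parents, replace = TRUE) - 1L)
  start <- (seq_len(n_parents) - 1L) * parent_s + offsets
  excluded <- rep(FALSE, n_parents)
  reason <- rep(NA_character_, n_parents)
  sz <- recording$seizure_intervals
  if (nrow(sz)) {
    for (i in seq_len(n_parents)) {
      hit <- any(start[i] < sz[, 2] & (start[i] + segment_s) > sz[, 1])
      if (hit) { excluded[i] <- TRUE; reason[i] <- "seizure" }
    }
  }
  data.frame(parent = seq_len(n_parents), start = start,
             duration = segment_s, stage = NA_character_,
             excluded = excluded, exclusion_reason = reason,
             stringsAsFactors = FALSE)
}

map_stage_label <- function(stage) {
  s <- toupper(trimws(as.character(stage)))
  out <- rep("other", length(s))
  out[s %in% c("W", "WAKE")] <- "wake"
  out[s %in% c("N2", "N3", "N2N3")] <- "N2N3"
  out
}

#' Assign a sleep/wake stage to each segment
#'
#' Two modes. With external per-epoch labels (e.g. from an automated iEEG
#' sleep stager), each segment takes the label of the epoch containing its
#' midpoint; labels map W to `wake`, N2/N3 to `N2N3`, and everything else
#' (N1, REM, transitions) to `other`, which is used in neither analysis
#' state. Without labels, a delta-power proxy stager is applied: a segment is
#' `N2N3` when the relative delta power (0.5--4 Hz over 0.5--80 Hz, common
#' average reference over the retained contacts, after filtering) is at least
#' `sleep_threshold`, `wake` when at most `wake_threshold`, else `other`.
#'
#' @param segments data.frame from [segment_record()].
#' @param recording,montage required for the proxy stager.
#' @param labels optional data.frame with columns `epoch_start_s`, `stage`
#'   covering every segment; epochs last until the next epoch start
#'   (the final one for `epoch_s` seconds).
#' @param epoch_s nominal epoch length for the final external epoch.
#' @param sleep_threshold,wake_threshold delta-ratio cutpoints.
#' @return `segments` with the `stage` column filled.
#' @export
assign_sleep_stage <- function(segments, recording = NULL, montage = NULL,
                               labels = NULL, epoch_s = 30,
                               sleep_threshold = 0.5, wake_threshold = 0.3) {
  if (!is.null(labels)) {
    labels <- labels[order(labels$epoch_start_s), , drop = FALSE]
    ends <- c(labels$epoch_start_s[-1],
              labels$epoch_start_s[nrow(labels)] + epoch_s)
    mid <- segments$start + segments$duration / 2
    idx <- findInterval(mid, labels$epoch_start_s)
    covered <- idx >= 1 & mid < ends[pmax(idx, 1)]
    if (any(!covered))
      stop("sleep labels do not cover segments: ",
           paste(which(!covered), collapse = ", "))
    segments$stage <- map_stage_label(labels$stage[idx])
    return(segments)
  }
  if (is.null(recording) || is.null(montage))
    stop("proxy staging needs the recording and montage")
  ref <- apply_reference(recording, montage, "car")
  fs <- recording$fs
  for (i in seq_len(nrow(segments))) {
    if (segments$excluded[i]) next
    x <- segment_signal(ref$recording, segments$start[i], segments$duration[i])
    x <- filter_signal(x, fs = fs)
    w <- welch_spectra(x, fs, keep_stft = FALSE)
    bb <- band_mask(w$freq, "bb"); dd <- band_mask(w$freq, "delta")
    ratio <- mean(colSums(w$psd[dd, , drop = FALSE]) /
                  colSums(w$psd[bb, , drop = FALSE]))
    segments$stage[i] <-
      if (!is.finite(ratio)) "other"
      else if (ratio >= sleep_threshold) "N2N3"
      else if (ratio <= wake_threshold) "wake"
      else "other"
  }
  segments
}
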