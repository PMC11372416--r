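#' Construct a multichannel iEEG recording
#'
#' The raw unit of analysis: a channels x time matrix of voltages (microvolts)
#' with a sampling rate, channel labels, a start time, and any clinically
#' annotated seizure intervals (seconds from record start, used to exclude
#' overlapping analysis segments).
#'
#' @param samples numeric matrix, channels in rows, samples in columns (uV).
#' @param fs sampling rate in Hz (> 0).
#' @param labels character vector of channel labels, one per row.
#' @param start_time record start (arbitrary origin), default 0.
#' @param seizure_intervals two-column matrix or data.frame of
#'   (start_s, end_s) seizure intervals, or `NULL`.
#' @return An object of class `ieeg_recording`.
#' @export
new_recording <- function(samples, fs, labels, start_time = 0,
                          seizure_intervals = NULL) {
  samples <- as.matrix(samples)
  if (!is.numeric(samples)) stop("samples must be numeric")
  if (length(fs) != 1L || !is.finite(fs) || fs <= 0) stop("fs must be > 0")
  labels <- as.character(labels)
  if (length(labels) != nrow(samples))
    stop("label count (", length(labels), ") != channel row count (",
         nrow(samples), ")")
  if (anyDuplicated(labels)) stop("duplicate channel labels")
  dur <- ncol(samples) / fs
  if (!is.null(seizure_intervals)) {
    seizure_intervals <- as.matrix(seizure_intervals)
    if (ncol(seizure_intervals) != 2L) stop("seizure_intervals needs 2 columns")
    if (any(seizure_intervals < 0) || any(seizure_intervals[, 2] > dur) ||
        any(seizure_intervals[, 1] >= seizure_intervals[, 2]))
      stop("seizure intervals must lie within record bounds")
  } else seizure_intervals <- matrix(numeric(0), ncol = 2)
  rownames(samples) <- labels
  structure(
    list(samples = samples, fs = fs, labels = labels, start_time = start_time,
         seizure_intervals = seizure_intervals),
    class = "ieeg_recording")
}

#' @export
print.ieeg_recording <- function(x, ...) {
  cat(sprintf("<ieeg_recording> %d channels x %.1f min @ %g Hz\n",
              nrow(x$samples), ncol(x$samples) / x$fs / 60, x$fs))
  cat("  channels:", paste(head(x$labels, 8), collapse = ", "),
      if (length(x$labels) > 8) "...", "\n")
  if (nrow(x$seizure_intervals))
    cat("  seizure intervals:", nrow(x$seizure_intervals), "\n")
  invisible(x)
}

#' Duration of a recording in seconds
#' @param recording an `ieeg_recording`.
#' @return numeric scalar, seconds.
#' @export
recording_duration <- function(recording) {
  ncol(recording$samples) / recording$fs
}

# slice [start_s, start_s + duration_s) as a time x channel matrix
segment_signal <- function(recording, start_s, duration_s = 60) {
  fs <- recording$fs
  i0 <- floor(start_s * fs) + 1L
  i1 <- i0 + round(duration_s * fs) - 1L
  if (i0 < 1L || i1 > ncol(recording$samples))
    stop("segment outside record bounds")
  t(recording$samples[, i0:i1, drop = FALSE])
}
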