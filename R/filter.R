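# 60 Hz notch (RBJ biquad, Q = 30) + 0.5-80 Hz zero-phase Butterworth bandpass.
# The bandpass is a cascade of 2nd-order high-pass and low-pass sections:
# a direct high-order bandpass with a 0.5 Hz edge is numerically fragile
# under filtfilt at clinical sampling rates.

# direct-form IIR y = (b/a) * x via the C filter primitives
iir_filter <- function(b, a, x) {
  v <- stats::filter(c(rep(x[1], length(b) - 1), x), b, method = "convolution",
                     sides = 1)
  v <- v[-seq_len(length(b) - 1)]
  if (length(a) > 1) v <- stats::filter(v, -a[-1], method = "recursive")
  as.numeric(v)
}

# zero-phase (forward-backward) filtering with odd-reflection edge padding
zp_filter <- function(filt, x) {
  b <- filt$b %||% filt[["b"]]; a <- filt$a %||% filt[["a"]]
  n <- length(x)
  pad <- min(n - 1L, max(3L * (max(length(a), length(b)) - 1L), 50L))
  pre <- 2 * x[1] - x[(pad + 1L):2]
  post <- 2 * x[n] - x[(n - 1L):(n - pad)]
  y <- c(pre, x, post)
  y <- iir_filter(b, a, y)
  y <- rev(iir_filter(b, a, rev(y)))
  y[(pad + 1L):(pad + n)]
}

as_ba <- function(f) list(b = as.numeric(f$b), a = as.numeric(f$a))

notch_coefficients <- function(f0, fs, Q = 30) {
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * Q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  list(b = b / a[1], a = a / a[1])
}

# Butterworth designs are cached per (type, fs, edges)
.filter_cache <- new.env(parent = emptyenv())
cached_butter <- function(order, W, type) {
  key <- paste(type, order, paste(signif(W, 12), collapse = "_"))
  f <- .filter_cache[[key]]
  if (is.null(f)) {
    f <- as_ba(signal::butter(order, W, type = type))
    .filter_cache[[key]] <- f
  }
  f
}

# zero-phase single-channel chain; x numeric vector
filter_vector <- function(x, fs, low = 0.5, high = 80, notch = 60, Q = 30) {
  x <- x - mean(x)                       # explicit DC removal
  if (!is.null(notch) && notch < fs / 2) {
    x <- zp_filter(notch_coefficients(notch, fs, Q), x)
  }
  x <- zp_filter(cached_butter(2, low / (fs / 2), "high"), x)
  zp_filter(cached_butter(2, high / (fs / 2), "low"), x)
}

#' Notch and bandpass filter a recording
#'
#' Applies, zero-phase (forward-backward, so spike timing is not skewed), a
#' 60 Hz notch (biquad, Q = 30) and a 0.5--80 Hz Butterworth bandpass to every
#' channel. DC is removed by the high-pass edge.
#'
#' @param recording an `ieeg_recording`, or a time x channel numeric matrix
#'   (then `fs` must be given).
#' @param fs sampling rate, only when `recording` is a bare matrix.
#' @param low,high bandpass edges in Hz.
#' @param notch notch frequency in Hz (`NULL` to skip).
#' @return Object of the same shape as the input, filtered.
#' @export
filter_signal <- function(recording, fs = NULL, low = 0.5, high = 80,
                          notch = 60) {
  is_rec <- inherits(recording, "ieeg_recording")
  if (is_rec) fs <- recording$fs
  if (is.null(fs)) stop("fs required for matrix input")
  if (fs <= 2 * high)
    stop("fs must exceed twice the bandpass upper edge (", high, " Hz)")
  if (fs <= 160)
    warning("fs <= 160 Hz: 80 Hz content is poorly resolved")
  if (is_rec) {
    x <- recording$samples
    for (i in seq_len(nrow(x)))
      x[i, ] <- filter_vector(x[i, ], fs, low, high, notch)
    recording$samples <- x
    recording
  } else {
    x <- as.matrix(recording)
    for (j in seq_len(ncol(x)))
      x[, j] <- filter_vector(x[, j], fs, low, high, notch)
    x
  }
}

# band-filter a vector (canonical band name or c(low, high)); broadband uses
# the main 0.5-80 chain without the notch (input is already notch-filtered)
band_filter <- function(x, band, fs) {
  e <- band_edges(band)
  if (e[2] >= fs / 2) stop("band above Nyquist")
  if (e[1] <= 0.6) {
    x <- zp_filter(cached_butter(2, e[1] / (fs / 2), "high"), x)
    zp_filter(cached_butter(2, e[2] / (fs / 2), "low"), x)
  } else {
    zp_filter(cached_butter(2, e / (fs / 2), "pass"), x)
  }
}
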