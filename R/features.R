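# Welch spectral machinery. 2-s Hann windows with 50% overlap resolve 0.5 Hz
# inside a 60-s segment; the windowed FFTs are cached so that auto-spectra,
# cross-spectra and coherence share one pass over the data.
welch_spectra <- function(x, fs, window_s = 2, overlap = 0.5,
                          keep_stft = TRUE) {
  x <- as.matrix(x)                      # time x channels
  n <- nrow(x); nch <- ncol(x)
  L <- round(window_s * fs)
  if (n < L) stop("segment shorter than one Welch window")
  hop <- max(1L, round(L * (1 - overlap)))
  starts <- seq(1L, n - L + 1L, by = hop)
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(L - 1)) / (L - 1))   # Hann
  nb <- L %/% 2 + 1L
  freq <- (0:(nb - 1)) * fs / L
  scale <- 1 / (fs * sum(w^2))
  stft <- if (keep_stft)
    array(complex(real = 0), dim = c(nb, length(starts), nch)) else NULL
  psd <- matrix(0, nb, nch)
  idx <- outer(0:(L - 1L), starts, "+")
  for (ch in seq_len(nch)) {
    seg <- matrix(x[idx, ch], nrow = L) * w
    F <- mvfft(seg)[seq_len(nb), , drop = FALSE]
    p <- rowMeans(Mod(F)^2) * scale
    p[-c(1, nb)] <- 2 * p[-c(1, nb)]     # one-sided
    psd[, ch] <- p
    if (keep_stft) stft[, , ch] <- F
  }
  list(freq = freq, psd = psd, stft = stft, scale = scale, n_windows =
         length(starts), nb = nb)
}

#' Line length of a signal
#'
#' Sum of absolute first differences, optionally normalized to a per-minute
#' rate (supply `fs`). A sensitive, cheap surrogate for combined amplitude and
#' frequency content, classically used on intracranial EEG.
#'
#' @param x numeric vector (>= 2 samples).
#' @param fs sampling rate; when given, the sum is scaled to per-minute units.
#' @return numeric scalar.
#' @export
#' @examples
#' line_length(c(0, 1, 3, 2))  # 4
line_length <- function(x, fs = NULL) {
  if (length(x) < 2) stop("line length needs at least 2 samples")
  ll <- sum(abs(diff(x)))
  if (!is.null(fs)) ll <- ll / ((length(x) - 1) / fs / 60)
  ll
}

#' Band power via Welch periodogram
#'
#' Integrates the Welch power spectral density over a frequency band.
#'
#' @param x numeric vector.
#' @param band canonical band name (see [canonical_bands()]) or `c(low, high)`.
#' @param fs sampling rate in Hz.
#' @param window_s,overlap Welch settings.
#' @return power in signal units squared.
#' @export
bandpower <- function(x, band, fs, window_s = 2, overlap = 0.5) {
  e <- band_edges(band)
  if (e[2] > fs / 2) stop("band above Nyquist")
  w <- welch_spectra(matrix(x, ncol = 1), fs, window_s, overlap,
                     keep_stft = FALSE)
  df <- w$freq[2] - w$freq[1]
  sum(w$psd[band_mask(w$freq, band), 1]) * df
}

#' Spectral entropy
#'
#' Shannon entropy of the Welch PSD over 0.5--80 Hz, treated as a probability
#' mass over frequency bins and normalized by `log(#bins)` so that white
#' noise approaches 1 and a pure tone approaches 0.
#'
#' @inheritParams bandpower
#' @return value in `[0, 1]`, or `NA` for a zero-power signal.
#' @export
spectral_entropy <- function(x, fs, window_s = 2, overlap = 0.5) {
  w <- welch_spectra(matrix(x, ncol = 1), fs, window_s, overlap,
                     keep_stft = FALSE)
  p <- w$psd[band_mask(w$freq, "bb"), 1]
  spectral_entropy_from_psd(p)
}

# entropy of a PSD mass vector, normalized to [0, 1]
spectral_entropy_from_psd <- function(p) {
  if (!length(p) || any(!is.finite(p)) || sum(p) <= 0) return(NA_real_)
  nb <- length(p)
  p <- p / sum(p)
  nz <- p > 0
  -sum(p[nz] * log(p[nz])) / log(nb)
}

#' Squared Pearson correlation of two signals
#'
#' @param x,y equal-length numeric vectors.
#' @return \eqn{r^2 \in [0, 1]}, `NA` if either signal has zero variance.
#' @export
pearson_sq <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2) stop("need equal lengths >= 2")
  if (sd(x) == 0 || sd(y) == 0) return(NA_real_)
  cor(x, y)^2
}

#' Maximum absolute lagged cross-correlation
#'
#' Maximum over integer lags `|l| <= max_lag` of the absolute Pearson
#' correlation between the overlapping parts of the two (time-shifted)
#' signals.
#'
#' @param x,y equal-length numeric vectors.
#' @param max_lag maximum lag in samples (< series length).
#' @return value in `[0, 1]`, `NA` if either overlap has zero variance at all
#'   lags.
#' @export
cross_corr <- function(x, y, max_lag) {
  n <- length(x)
  if (length(y) != n) stop("need equal lengths")
  if (max_lag >= n) stop("max_lag must be below the series length")
  # FFT cross-products plus cumulative sums give the exact per-lag Pearson
  # correlation of the overlapping windows in O(n log n)
  L <- stats::nextn(2 * n)
  X <- fft(c(x, numeric(L - n))); Y <- fft(c(y, numeric(L - n)))
  cc <- Re(fft(Conj(X) * Y, inverse = TRUE)) / L  # cc[l+1] = sum x[t] y[t+l]
  cx <- cumsum(x); cxx <- cumsum(x^2)
  cy <- cumsum(y); cyy <- cumsum(y^2)
  best <- NA_real_
  for (l in -max_lag:max_lag) {
    m <- n - abs(l)
    if (l >= 0) {
      sxy <- cc[l + 1]
      sx <- cx[m]; sxx <- cxx[m]
      sy <- cy[n] - if (l > 0) cy[l] else 0
      syy <- cyy[n] - if (l > 0) cyy[l] else 0
    } else {
      sxy <- cc[L + l + 1]                  # sum x[t] y[t + l], l < 0
      sx <- cx[n] - cx[-l]; sxx <- cxx[n] - cxx[-l]
      sy <- cy[m]; syy <- cyy[m]
    }
    vx <- sxx - sx^2 / m; vy <- syy - sy^2 / m
    if (vx <= 0 || vy <= 0) next
    r <- abs((sxy - sx * sy / m) / sqrt(vx * vy))
    if (is.na(best) || r > best) best <- r
  }
  best
}

#' Magnitude-squared coherence averaged over a band
#'
#' Welch estimate \eqn{|S_{xy}|^2 / (S_{xx} S_{yy})}, averaged over the
#' frequency bins of the band.
#'
#' @inheritParams bandpower
#' @param y second signal.
#' @return value in `[0, 1]`.
#' @export
coherence <- function(x, y, band, fs, window_s = 2, overlap = 0.5) {
  e <- band_edges(band)
  if (e[2] > fs / 2) stop("band above Nyquist")
  w <- welch_spectra(cbind(x, y), fs, window_s, overlap)
  coherence_from_stft(w, 1, 2, band)
}

coherence_from_stft <- function(w, i, j, band) {
  coherence_bands_from_stft(w$stft[, , i], w$stft[, , j], w$freq, band)
}

# coherence spectrum computed once, then averaged per requested band
coherence_bands_from_stft <- function(Fi, Fj, freq, bands) {
  Sxy <- rowMeans(Fi * Conj(Fj))
  Sxx <- rowMeans(Mod(Fi)^2); Syy <- rowMeans(Mod(Fj)^2)
  C <- Mod(Sxy)^2 / (Sxx * Syy)
  out <- vapply(bands, function(b) {
    m <- band_mask(freq, b)
    mean(C[m & is.finite(C)])
  }, numeric(1))
  if (length(bands) == 1L) unname(out) else out
}

# one-sided PSD matrix (bins x channels) from an STFT tensor
psd_from_stft <- function(stft, scale) {
  nb <- dim(stft)[1]
  psd <- apply(stft, 3, function(F) rowMeans(Mod(F)^2)) * scale
  psd <- matrix(psd, nrow = nb)
  psd[-c(1, nb), ] <- 2 * psd[-c(1, nb), ]
  psd
}

# analytic-signal instantaneous phase (frequency-domain Hilbert transform)
analytic_phase <- function(x) {
  n <- length(x)
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) { h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2 }
  else { h[1] <- 1; h[2:((n + 1) / 2)] <- 2 }
  Arg(fft(X * h, inverse = TRUE) / n)
}

#' Phase-locking value in a band
#'
#' Band-filters both signals, extracts analytic-signal phases, and returns
#' \eqn{|mean_t e^{i(\phi_x - \phi_y)}|}. The first and last `edge_s` seconds
#' of phase are discarded to suppress filter/Hilbert edge effects.
#'
#' @inheritParams coherence
#' @param edge_s seconds trimmed from each end of the phase series.
#' @return value in `[0, 1]`, `NA` for a degenerate (zero) band signal.
#' @export
plv <- function(x, y, band, fs, edge_s = 0.5) {
  xf <- band_filter(x, band, fs); yf <- band_filter(y, band, fs)
  if (sd(xf) == 0 || sd(yf) == 0) return(NA_real_)
  plv_from_phases(analytic_phase(xf), analytic_phase(yf),
                  trim = round(edge_s * fs))
}

plv_from_phases <- function(px, py, trim = 0) {
  n <- length(px)
  if (trim > 0 && n > 2 * trim + 2) {
    keep <- (trim + 1):(n - trim)
    px <- px[keep]; py <- py[keep]
  }
  Mod(mean(exp(1i * (px - py))))
}

#' Relative entropy between two band-filtered amplitude distributions
#'
#' Symmetrized Kullback--Leibler divergence
#' \eqn{\tfrac12[KL(p\|q) + KL(q\|p)]} between amplitude histograms of the
#' two band-filtered signals, on shared bin edges spanning the pooled range,
#' with additive smoothing before normalization.
#'
#' @inheritParams coherence
#' @param bins number of histogram bins.
#' @param smoothing additive (Laplace) smoothing added to each bin count.
#' @return non-negative value; 0 for identical inputs.
#' @export
relative_entropy <- function(x, y, band, fs, bins = 30, smoothing = 1e-6) {
  xf <- band_filter(x, band, fs); yf <- band_filter(y, band, fs)
  relative_entropy_hist(xf, yf, bins, smoothing)
}

relative_entropy_hist <- function(xf, yf, bins = 30, smoothing = 1e-6) {
  rng <- range(c(xf, yf), finite = TRUE)
  if (!all(is.finite(rng)) || diff(rng) == 0) return(NA_real_)
  edges <- seq(rng[1], rng[2], length.out = bins + 1L)
  cx <- tabulate(pmin(findInterval(xf, edges, rightmost.closed = TRUE), bins),
                 nbins = bins)
  cy <- tabulate(pmin(findInterval(yf, edges, rightmost.closed = TRUE), bins),
                 nbins = bins)
  p <- (cx + smoothing) / sum(cx + smoothing)
  q <- (cy + smoothing) / sum(cy + smoothing)
  0.5 * (sum(p * log(p / q)) + sum(q * log(q / p)))
}
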