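#' Canonical EEG frequency bands
#'
#' Band edges (Hz) used throughout the package. Broadband is 0.5--80 Hz, the
#' canonical bands are delta 0.5--4, theta 4--8, alpha 8--12, beta 12--30 and
#' gamma 30--80 Hz. When integrating spectra, a frequency bin \eqn{f} belongs
#' to a canonical band when \eqn{low \le f < high} (so adjacent bands
#' partition the axis); broadband is inclusive at both edges.
#'
#' @return Named list of length-2 numeric vectors `c(low, high)`.
#' @export
#' @examples
#' canonical_bands()$alpha
canonical_bands <- function() {
  list(
    bb    = c(0.5, 80),
    delta = c(0.5, 4),
    theta = c(4, 8),
    alpha = c(8, 12),
    beta  = c(12, 30),
    gamma = c(30, 80)
  )
}

band_edges <- function(band) {
  if (is.numeric(band) && length(band) == 2L) {
    if (!(band[1] > 0 && band[1] < band[2])) stop("invalid band edges")
    return(as.numeric(band))
  }
  bands <- canonical_bands()
  if (!is.character(band) || !band %in% names(bands))
    stop("unknown band: ", paste(band, collapse = ", "))
  bands[[band]]
}

# frequency-bin membership used for all band integrations
band_mask <- function(freq, band) {
  e <- band_edges(band)
  if (is.character(band) && identical(band, "bb")) freq >= e[1] & freq <= e[2]
  else freq >= e[1] & freq < e[2]
}
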