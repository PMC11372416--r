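#' Parse iEEG channel labels into a montage table
#'
#' Applies the default stereo-EEG naming grammar: a leading `L` or `R` gives
#' the hemisphere, a trailing integer the contact index, and the remainder the
#' electrode name (so `"LA1"` is contact 1 of left electrode A). Labels that
#' do not parse (e.g. `"EKG"`) get hemisphere `"unknown"` and are never
#' retained for analysis. The contralateral partner of each contact is the
#' same electrode name and contact index with the hemisphere letter swapped.
#'
#' @param labels character vector of channel labels (no duplicates).
#' @param temporal named logical vector or `NULL`. Per-label flag marking
#'   temporal-lobe contacts (from an electrode metadata table). Default `NULL`
#'   marks every parseable contact temporal.
#' @return A `channel_montage` data.frame with columns `label`, `hemisphere`
#'   (`"L"`, `"R"` or `"unknown"`), `electrode`, `contact`, `temporal`,
#'   `artifact`, `partner` (contralateral label or `NA`), `retained`.
#' @export
#' @examples
#' parse_channel_labels(c("LA1", "LA2", "RA1", "RA2", "EKG"))
parse_channel_labels <- function(labels, temporal = NULL) {
  labels <- as.character(labels)
  if (!length(labels)) stop("empty label list")
  if (anyDuplicated(labels))
    stop("duplicate labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  m <- regmatches(labels, regexec("^([LR])([A-Za-z']*?)([0-9]+)$", labels))
  hemi <- electrode <- rep("unknown", length(labels))
  contact <- rep(NA_integer_, length(labels))
  ok <- lengths(m) == 4L
  if (any(ok)) {
    parts <- do.call(rbind, m[ok])
    hemi[ok] <- parts[, 2]
    electrode[ok] <- paste0(parts[, 2], parts[, 3])
    contact[ok] <- as.integer(parts[, 4])
  }
  if (is.null(temporal)) temporal <- ok
  else {
    if (is.null(names(temporal))) {
      if (length(temporal) != length(labels))
        stop("temporal flags must be named or match label length")
      names(temporal) <- labels
    }
    temporal <- as.logical(temporal[labels])
    temporal[is.na(temporal)] <- FALSE
    temporal <- temporal & ok
  }
  partner <- rep(NA_character_, length(labels))
  other <- ifelse(hemi == "L", "R", "L")
  cand <- ifelse(ok, paste0(other, sub("^[LR]", "", electrode), contact), NA)
  partner[ok] <- ifelse(cand[ok] %in% labels, cand[ok], NA)
  out <- data.frame(
    label = labels, hemisphere = hemi, electrode = electrode,
    contact = contact, temporal = as.logical(temporal),
    artifact = FALSE, partner = partner, retained = FALSE,
    stringsAsFactors = FALSE)
  class(out) <- c("channel_montage", "data.frame")
  out
}

#' Flag artifact-contaminated or dead channels
#'
#' Deterministic stand-in for a manual/algorithmic artifact review: a channel
#' is flagged when its robust amplitude (median absolute deviation) exceeds
#' `mad_mult` times the cross-channel median MAD, when its 60 Hz relative
#' power (58--62 Hz over 0.5--80 Hz) exceeds `line_ratio`, or when it is flat
#' (zero MAD, a dead contact).
#'
#' @param recording an `ieeg_recording`.
#' @param montage a `channel_montage` from [parse_channel_labels()].
#' @param mad_mult amplitude threshold as a multiple of the median MAD.
#' @param line_ratio maximal tolerated 60 Hz relative power.
#' @param max_seconds at most this much leading signal is inspected.
#' @return The montage with its `artifact` column updated.
#' @export
detect_artifact_channels <- function(recording, montage, mad_mult = 10,
                                     line_ratio = 0.5, max_seconds = 300) {
  fs <- recording$fs
  n <- min(ncol(recording$samples), round(max_seconds * fs))
  if (n < 60 * fs) {
    if (n < 1 * fs) stop("need at least 1 min of data")
  }
  x <- recording$samples[montage$label, seq_len(n), drop = FALSE]
  mads <- apply(x, 1, mad)
  med <- median(mads[mads > 0])
  flag_amp <- if (is.finite(med) && med > 0) mads > mad_mult * med
              else rep(FALSE, length(mads))
  flag_dead <- mads == 0
  flag_line <- rep(FALSE, nrow(x))
  for (i in seq_len(nrow(x))) {
    if (flag_dead[i]) next
    w <- welch_spectra(matrix(x[i, ], ncol = 1), fs, keep_stft = FALSE)
    tot <- sum(w$psd[band_mask(w$freq, "bb"), 1])
    line <- sum(w$psd[w$freq >= 58 & w$freq <= 62, 1])
    if (tot > 0 && line / tot > line_ratio) flag_line[i] <- TRUE
  }
  montage$artifact <- flag_amp | flag_dead | flag_line
  if (all(montage$artifact)) stop("all channels flagged as artifact")
  montage
}

#' Select symmetric bilateral temporal contacts
#'
#' Keeps exactly those contacts that are temporal, artifact-free, and whose
#' mirror-image contact on the other hemisphere is present, temporal and
#' artifact-free. Restricting analysis to symmetric pairs removes the
#' inter-contact-distance confound from connectivity comparisons, and makes
#' the retained set hemisphere-balanced by construction.
#'
#' @param montage a `channel_montage` (after any artifact flagging).
#' @return The montage with its `retained` column set.
#' @export
select_symmetric_temporal <- function(montage) {
  eligible <- montage$temporal & !montage$artifact &
    montage$hemisphere %in% c("L", "R") & !is.na(montage$partner)
  ok <- setNames(eligible, montage$label)
  montage$retained <- eligible & unname(ok[montage$partner])
  montage$retained[is.na(montage$retained)] <- FALSE
  nl <- sum(montage$retained & montage$hemisphere == "L")
  nr <- sum(montage$retained & montage$hemisphere == "R")
  if (nl == 0 || nr == 0) stop("no bilateral temporal coverage")
  stopifnot(nl == nr)  # invariant: symmetric retention
  montage
}
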