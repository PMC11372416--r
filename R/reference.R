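# Every reference scheme is a linear combination of the retained machine
# channels: machine = identity, common average = I - J/m, bipolar = signed
# adjacent-contact differences. The combination matrix lets downstream code
# derive referenced signals (and their spectra, which are linear in the
# signal) from one filtered copy of the data.
reference_matrix <- function(montage, scheme = c("mac", "car", "bi")) {
  scheme <- match.arg(scheme[1], c("mac", "car", "bi", "machine", "bipolar"))
  if (scheme == "machine") scheme <- "mac"
  if (scheme == "bipolar") scheme <- "bi"
  keep <- montage[montage$retained, , drop = FALSE]
  if (!nrow(keep)) stop("retained set is empty")
  m <- nrow(keep)
  if (scheme == "mac") {
    A <- diag(m); labels <- keep$label; side <- keep$hemisphere
  } else if (scheme == "car") {
    A <- diag(m) - 1 / m
    labels <- keep$label; side <- keep$hemisphere
  } else {
    next_lab <- paste0(keep$electrode, keep$contact + 1L)
    have <- which(next_lab %in% keep$label)
    if (!length(have)) stop("bipolar reference: no adjacent contact pairs")
    A <- matrix(0, m, length(have))
    for (k in seq_along(have)) {
      A[have[k], k] <- 1
      A[match(next_lab[have[k]], keep$label), k] <- -1
    }
    labels <- paste0(keep$label[have], "-", next_lab[have])
    side <- keep$hemisphere[have]
    if (!all(c("L", "R") %in% side))
      stop("bipolar reference: one hemisphere empty")
  }
  list(A = A, labels = labels, side = setNames(side, labels),
       input = keep$label, scheme = scheme)
}

#' Re-reference a recording over the retained contacts
#'
#' Referencing is applied after symmetric temporal-contact selection, over the
#' retained set only. `"mac"` (machine reference) keeps channels as recorded;
#' `"car"` subtracts the per-sample mean of all retained channels from each;
#' `"bi"` (bipolar) takes the difference between adjacent contacts on the same
#' electrode (contact i minus contact i+1), dropping contacts whose neighbour
#' is not retained, with output labels like `"LA1-LA2"`.
#'
#' @param recording an `ieeg_recording`.
#' @param montage a `channel_montage` with `retained` set
#'   (see [select_symmetric_temporal()]).
#' @param scheme one of `"mac"`, `"car"`, `"bi"` (aliases `"machine"`,
#'   `"bipolar"` accepted).
#' @return A list with `recording` (the referenced `ieeg_recording`) and
#'   `side` (named vector giving each output channel's hemisphere).
#' @export
#' @examples
#' rec <- new_recording(rbind(c(1, 1), c(3, 3)), fs = 200, c("LA1", "RA1"))
#' mont <- select_symmetric_temporal(parse_channel_labels(rec$labels))
#' apply_reference(rec, mont, "car")$recording$samples
apply_reference <- function(recording, montage,
                            scheme = c("mac", "car", "bi")) {
  rm_ <- reference_matrix(montage, scheme)
  x <- recording$samples[rm_$input, , drop = FALSE]
  out <- crossprod(rm_$A, x)
  rec <- new_recording(out, recording$fs, rm_$labels, recording$start_time,
                       if (nrow(recording$seizure_intervals))
                         recording$seizure_intervals else NULL)
  list(recording = rec, side = rm_$side, scheme = rm_$scheme)
}
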