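# Minimal EDF (European Data Format) I/O: fixed-width ASCII header plus
# 16-bit little-endian samples, one data record per second. Covers the
# plain continuous-recording subset of the format (no annotations).

edf_pad <- function(s, n) {
  s <- substr(as.character(s), 1, n)
  sprintf("%-*s", n, s)
}

#' Write a recording to an EDF file
#'
#' @param recording an `ieeg_recording` with an integer number of samples
#'   per second.
#' @param path output file.
#' @param patient,recording_id header identification fields.
#' @return `path`, invisibly.
#' @export
write_edf <- function(recording, path, patient = "X", recording_id = "X") {
  fs <- recording$fs
  if (abs(fs - round(fs)) > 1e-9) stop("EDF writer needs integer fs")
  fs <- as.integer(round(fs))
  x <- recording$samples
  n_rec <- floor(ncol(x) / fs)
  if (n_rec < 1) stop("record shorter than one EDF data record")
  x <- x[, seq_len(n_rec * fs), drop = FALSE]
  ns <- nrow(x)
  pmin_ <- apply(x, 1, min); pmax_ <- apply(x, 1, max)
  flat <- pmax_ - pmin_ < 1e-12
  pmax_[flat] <- pmin_[flat] + 1
  dmin <- -32768; dmax <- 32767
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8), edf_pad(patient, 80), edf_pad(recording_id, 80),
    edf_pad("01.01.00", 8), edf_pad("00.00.00", 8),
    edf_pad(256 + ns * 256, 8), edf_pad("", 44),
    edf_pad(n_rec, 8), edf_pad("1", 8), edf_pad(ns, 4))
  writeChar(hdr, con, eos = NULL)
  field <- function(vals, w) writeChar(paste0(vapply(vals, edf_pad, "",
                                                     n = w), collapse = ""),
                                       con, eos = NULL)
  field(recording$labels, 16)
  field(rep("", ns), 80)
  field(rep("uV", ns), 8)
  field(formatC(pmin_, digits = 7, width = 8, format = "g"), 8)
  field(formatC(pmax_, digits = 7, width = 8, format = "g"), 8)
  field(rep(dmin, ns), 8)
  field(rep(dmax, ns), 8)
  field(rep("", ns), 80)
  field(rep(fs, ns), 8)
  field(rep("", ns), 32)
  pmin_num <- as.numeric(formatC(pmin_, digits = 7, width = 8, format = "g"))
  pmax_num <- as.numeric(formatC(pmax_, digits = 7, width = 8, format = "g"))
  gain <- (pmax_num - pmin_num) / (dmax - dmin)
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1) * fs + 1):(r * fs)
    for (ch in seq_len(ns)) {
      dig <- round((x[ch, cols] - pmin_num[ch]) / gain[ch]) + dmin
      writeBin(as.integer(pmin(pmax(dig, dmin), dmax)), con, size = 2,
               endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF file written by [write_edf()] (or any plain continuous EDF)
#'
#' @param path EDF file.
#' @return an `ieeg_recording` (all signals must share one sampling rate).
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) readChar(con, n, useBytes = TRUE)
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8)                       # header bytes
  rd(44)
  n_rec <- as.integer(rd(8)); rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  rdv <- function(w) vapply(seq_len(ns), function(i) trimws(rd(w)), "")
  labels <- rdv(16); rdv(80); rdv(8)
  pmin_ <- as.numeric(rdv(8)); pmax_ <- as.numeric(rdv(8))
  dmin <- as.numeric(rdv(8)); dmax <- as.numeric(rdv(8))
  rdv(80)
  spr <- as.integer(rdv(8)); rdv(32)
  if (length(unique(spr)) != 1) stop("mixed sampling rates unsupported")
  fs <- spr[1] / rec_dur
  gain <- (pmax_ - pmin_) / (dmax - dmin)
  x <- matrix(0, ns, n_rec * spr[1])
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1) * spr[1] + 1):(r * spr[1])
    for (ch in seq_len(ns)) {
      dig <- readBin(con, "integer", spr[1], size = 2, endian = "little")
      x[ch, cols] <- (dig - dmin[ch]) * gain[ch] + pmin_[ch]
    }
  }
  new_recording(x, fs, labels)
}

#' Export a synthetic cohort to standard on-disk formats
#'
#' Writes one EDF per patient, a channel metadata CSV (`label, hemisphere,
#' electrode, contact, temporal_flag`), a cohort clinical CSV (`patient_id,
#' laterality, surgery_side, engel, ilae`), and the ground truth (including
#' injected spike times) as JSON.
#'
#' @param cohort a materialized `sim_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (is.null(cohort$recordings)) stop("cohort must be materialized")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  clin <- data.frame(
    patient_id = vapply(cohort$truths, `[[`, "", "patient_id"),
    laterality = vapply(cohort$truths, `[[`, "", "true_laterality"),
    surgery_side = vapply(cohort$truths, `[[`, "", "surgery_side"),
    engel = vapply(cohort$truths, function(t) as.numeric(t$engel), 1),
    ilae = vapply(cohort$truths, function(t) as.numeric(t$ilae), 1))
  write.csv(clin, file.path(dir, "clinical.csv"), row.names = FALSE)
  for (i in seq_along(cohort$recordings)) {
    rec <- cohort$recordings[[i]]
    id <- cohort$truths[[i]]$patient_id
    write_edf(rec, file.path(dir, paste0(id, ".edf")))
    mont <- parse_channel_labels(rec$labels)
    write.csv(data.frame(label = mont$label, hemisphere = mont$hemisphere,
                         electrode = mont$electrode, contact = mont$contact,
                         temporal_flag = mont$temporal),
              file.path(dir, paste0(id, "_channels.csv")),
              row.names = FALSE)
  }
  truth <- lapply(cohort$truths, function(t) unclass(t))
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Write an AI matrix as long- or wide-format CSV
#'
#' @param ai patients x features matrix.
#' @param path output CSV; missing values are written as empty cells.
#' @return `path`, invisibly.
#' @export
write_ai_matrix <- function(ai, path) {
  df <- data.frame(patient_id = rownames(ai) %||% seq_len(nrow(ai)),
                   as.data.frame(ai, check.names = FALSE))
  write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}
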