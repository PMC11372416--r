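#' End-to-end per-patient asymmetry-index extraction
#'
#' Runs the complete conditioning and feature pipeline on one recording:
#' label parsing, artifact-channel rejection, symmetric temporal-contact
#' selection, random one-minute segmentation, sleep staging (external labels
#' when supplied, else the delta-power proxy), feature-grid computation for
#' every requested reference and state, and collapse to the asymmetry-index
#' vector.
#'
#' @param recording an `ieeg_recording`.
#' @param temporal named logical vector of temporal-contact flags
#'   (default: every parseable contact).
#' @param sleep_labels optional external stage table
#'   (see [assign_sleep_stage()]).
#' @param config a [feature_config()].
#' @param seed segment-draw seed.
#' @param artifact_check run [detect_artifact_channels()] (default TRUE).
#' @return list with `ai` (named AI vector), `grid`, `segments`, `montage`.
#' @export
patient_ai <- function(recording, temporal = NULL, sleep_labels = NULL,
                       config = feature_config(), seed = 1,
                       artifact_check = TRUE) {
  montage <- parse_channel_labels(recording$labels, temporal)
  if (artifact_check)
    montage <- detect_artifact_channels(recording, montage)
  montage <- select_symmetric_temporal(montage)
  segments <- segment_record(recording, seed = seed)
  segments <- assign_sleep_stage(segments, recording = recording,
                                 montage = montage, labels = sleep_labels)
  grid <- compute_feature_grid(recording, montage, segments, config)
  list(ai = ai_from_grid(grid), grid = grid, segments = segments,
       montage = montage)
}

#' Per-segment sleep spike counts for one patient
#'
#' The light-weight spike-only path: conditions the recording (default
#' common average reference), detects spikes on every usable N2/N3 sleep
#' segment, and returns the channel x segment count matrix used for
#' spike-rate AIs and the duration-subsampling analysis.
#'
#' @inheritParams patient_ai
#' @param reference `"mac"`, `"car"` or `"bi"`.
#' @param state `"sleep"` or `"wake"`.
#' @param detector [spike_detect_params()].
#' @return integer matrix channels x segments with attribute `side`
#'   (per-channel hemisphere); zero columns when the state has no usable
#'   segments.
#' @export
sleep_spike_counts <- function(recording, temporal = NULL,
                               sleep_labels = NULL, reference = "car",
                               state = "sleep",
                               detector = spike_detect_params(), seed = 1,
                               artifact_check = TRUE) {
  montage <- parse_channel_labels(recording$labels, temporal)
  if (artifact_check)
    montage <- detect_artifact_channels(recording, montage)
  montage <- select_symmetric_temporal(montage)
  segments <- segment_record(recording, seed = seed)
  segments <- assign_sleep_stage(segments, recording = recording,
                                 montage = montage, labels = sleep_labels)
  rr <- apply_reference(recording, montage, reference)
  labs <- names(rr$side)
  use <- which(!segments$excluded &
                 segments$stage == state_stage(state))
  counts <- matrix(0L, length(labs), length(use),
                   dimnames = list(labs, NULL))
  for (k in seq_along(use)) {
    si <- use[k]
    x <- segment_signal(rr$recording, segments$start[si],
                        segments$duration[si])
    x <- filter_signal(x, fs = recording$fs)
    for (ch in seq_along(labs))
      counts[ch, k] <- nrow(detect_spikes(x[, ch], recording$fs, detector))
  }
  attr(counts, "side") <- unname(rr$side)
  counts
}

#' Spike-rate asymmetry indices for a synthetic cohort
#'
#' Generates (or reuses) each patient's recording, runs the spike-only
#' pipeline, and assembles the single-feature cohort dataset
#' (`spikes__bb__car__sleep`) together with the clinical ground truth.
#'
#' @param cohort a `sim_cohort` from [generate_cohort()].
#' @param reference,state,detector passed to [sleep_spike_counts()].
#' @param seed segment-draw seed (per patient, offset by index).
#' @param keep_counts also return the per-patient count matrices (needed for
#'   [duration_subsample_experiment()]).
#' @return a [cohort_dataset()] with one AI column; when `keep_counts`, the
#'   matrices are attached as attribute `counts`.
#' @export
cohort_spike_ai <- function(cohort, reference = "car", state = "sleep",
                            detector = spike_detect_params(), seed = 1,
                            keep_counts = FALSE) {
  n <- length(cohort$truths)
  ai <- numeric(n)
  counts_list <- if (keep_counts) vector("list", n) else NULL
  for (i in seq_len(n)) {
    rec <- if (!is.null(cohort$recordings)) cohort$recordings[[i]]
           else generate_recording(cohort$config, cohort$truths[[i]])
    cm <- sleep_spike_counts(rec, reference = reference, state = state,
                             detector = detector, seed = seed + i)
    side <- attr(cm, "side")
    rates <- if (ncol(cm)) rowSums(cm) / ncol(cm)
             else rep(NA_real_, nrow(cm))
    ai[i] <- asymmetry_index(mean(rates[side == "L"]),
                             mean(rates[side == "R"]))
    if (keep_counts) counts_list[[i]] <- cm
  }
  m <- matrix(ai, ncol = 1, dimnames = list(
    vapply(cohort$truths, `[[`, "", "patient_id"),
    "spikes__bb__car__sleep"))
  ds <- cohort_dataset(
    m, vapply(cohort$truths, `[[`, "", "true_laterality"),
    surgery_side = vapply(cohort$truths, `[[`, "", "surgery_side"),
    engel = vapply(cohort$truths, function(t) as.numeric(t$engel), 1),
    ilae = vapply(cohort$truths, function(t) as.numeric(t$ilae), 1))
  if (keep_counts) attr(ds, "counts") <- counts_list
  ds
}

#' Full-grid asymmetry indices for a synthetic cohort
#'
#' Runs [patient_ai()] on every patient and stacks the AI vectors into a
#' cohort dataset with the canonical 180 columns (or a configured subset).
#'
#' @inheritParams cohort_spike_ai
#' @param config a [feature_config()].
#' @return a [cohort_dataset()].
#' @export
cohort_ai <- function(cohort, config = feature_config(), seed = 1) {
  n <- length(cohort$truths)
  ai_list <- vector("list", n)
  for (i in seq_len(n)) {
    rec <- if (!is.null(cohort$recordings)) cohort$recordings[[i]]
           else generate_recording(cohort$config, cohort$truths[[i]])
    ai_list[[i]] <- patient_ai(rec, config = config, seed = seed + i)$ai
  }
  names(ai_list) <- vapply(cohort$truths, `[[`, "", "patient_id")
  bm <- build_ai_matrix(ai_list)
  cohort_dataset(
    bm$ai, vapply(cohort$truths, `[[`, "", "true_laterality"),
    surgery_side = vapply(cohort$truths, `[[`, "", "surgery_side"),
    engel = vapply(cohort$truths, function(t) as.numeric(t$engel), 1),
    ilae = vapply(cohort$truths, function(t) as.numeric(t$ilae), 1))
}
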