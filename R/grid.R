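# The full feature grid: 6 broadband-only features (line length, spike rate,
# recruitment latency, spectral entropy, Pearson r^2, cross-correlation) plus
# 4 multi-frequency features (bandpower, coherence, PLV, relative entropy)
# over broadband + 5 canonical bands, each under 3 references and 2 sleep
# states: (6 + 4 x 6) x 3 x 2 = 180 cells.

FEATURES_SINGLE <- c("ll", "spikes", "rl", "se", "pearson", "xcor")
FEATURES_MULTI  <- c("bp", "coh", "plv", "re")
FEATURES_PAIR   <- c("pearson", "xcor", "coh", "plv", "re")
REFS_ALL        <- c("mac", "car", "bi")
STATES_ALL      <- c("wake", "sleep")

state_stage <- function(state) c(wake = "wake", sleep = "N2N3")[state]

#' Canonical asymmetry-index feature keys
#'
#' Enumerates the grid cells as `feature__band__reference__state` keys, in
#' canonical order (feature, then band, then reference `mac`/`car`/`bi`, then
#' state `wake`/`sleep`). The full grid has exactly 180 keys.
#'
#' @param features,references,states optional subsets.
#' @return character vector of keys.
#' @export
#' @examples
#' length(ai_feature_keys())  # 180
ai_feature_keys <- function(features = NULL, references = REFS_ALL,
                            states = STATES_ALL) {
  feats <- c(FEATURES_SINGLE, FEATURES_MULTI)
  if (!is.null(features)) feats <- feats[feats %in% features]
  keys <- character(0)
  for (f in feats) {
    bands <- if (f %in% FEATURES_MULTI) names(canonical_bands()) else "bb"
    for (b in bands) for (r in references) for (s in states)
      keys <- c(keys, paste(f, b, r, s, sep = "__"))
  }
  keys
}

#' Feature-grid computation settings
#'
#' @param references subset of `c("mac", "car", "bi")`.
#' @param states subset of `c("wake", "sleep")`.
#' @param features subset of the 10 feature codes (`NULL` = all).
#' @param window_s,overlap Welch settings.
#' @param max_lag_ms cross-correlation maximal lag.
#' @param re_bins,re_smoothing relative-entropy histogram settings.
#' @param gap_ms spike-sequence linkage gap.
#' @param detector spike detector parameters ([spike_detect_params()]).
#' @return named list of settings.
#' @export
feature_config <- function(references = REFS_ALL, states = STATES_ALL,
                           features = NULL, window_s = 2, overlap = 0.5,
                           max_lag_ms = 200, re_bins = 30,
                           re_smoothing = 1e-6, gap_ms = 100,
                           detector = spike_detect_params()) {
  list(references = references, states = states, features = features,
       window_s = window_s, overlap = overlap, max_lag_ms = max_lag_ms,
       re_bins = re_bins, re_smoothing = re_smoothing, gap_ms = gap_ms,
       detector = detector)
}

# intra-hemispheric (i, j) index pairs, i < j, in canonical order
intra_side_pairs <- function(side) {
  out <- NULL
  for (s in c("L", "R")) {
    ix <- which(side == s)
    if (length(ix) >= 2) out <- cbind(out, utils::combn(ix, 2))
  }
  out
}

#' Compute the per-patient interictal feature grid
#'
#' For every requested (reference, state) combination, computes each feature
#' on every non-excluded one-minute segment of that state and averages across
#' segments. Univariate cells are per-channel vectors; bivariate cells are
#' symmetric channel x channel matrices filled over intra-hemispheric pairs
#' (cross-hemisphere pairs are excluded from side aggregation and left `NA`).
#' Spike rate is pooled events per state-minute; recruitment latency averages
#' each channel's sequence latencies over the state. Cells with no usable
#' segments are missing.
#'
#' Internally each segment is filtered once in the machine reference and the
#' common-average and bipolar versions (and their Welch spectra) are derived
#' by the reference combination matrices, which is exact because referencing
#' is linear and time-invariant.
#'
#' @param recording an `ieeg_recording` (unfiltered; filtering is applied per
#'   segment after symmetric-contact selection).
#' @param montage retained-set montage (see [select_symmetric_temporal()]).
#' @param segments staged segment table (see [assign_sleep_stage()]).
#' @param config settings from [feature_config()].
#' @return A `feature_grid` object: list with `cells` (named list keyed
#'   `feature__band__ref__state`), `side` (per-reference channel sides),
#'   `states_n` (usable segment counts), `config`, `keys`.
#' @export
compute_feature_grid <- function(recording, montage, segments,
                                 config = feature_config()) {
  feats <- config$features %||% c(FEATURES_SINGLE, FEATURES_MULTI)
  states <- config$states
  refs <- config$references
  fs <- recording$fs
  usable <- !segments$excluded & segments$stage %in% state_stage(states)
  if (!any(usable)) stop("no usable segments in any requested state")
  bands <- names(canonical_bands())
  need_pairs <- any(feats %in% FEATURES_PAIR)
  need_spk <- any(c("spikes", "rl") %in% feats)
  need_welch <- any(c("bp", "se", "coh") %in% feats)
  need_bandfilt <- any(c("plv", "re") %in% feats)
  max_lag <- round(config$max_lag_ms / 1000 * fs)
  plv_trim <- round(0.5 * fs)
  refinfo <- lapply(setNames(refs, refs), reference_matrix,
                    montage = montage)
  pairsinfo <- lapply(refinfo, function(ri)
    if (need_pairs) intra_side_pairs(ri$side) else NULL)
  cells <- list()
  states_n <- setNames(integer(length(states)), states)
  for (st in states) {
    seg_idx <- which(!segments$excluded & segments$stage == state_stage(st))
    states_n[st] <- length(seg_idx)
    acc <- list(); nacc <- list()
    add <- function(key, val) {
      ok <- 0 + !is.na(val)
      if (is.null(acc[[key]])) {
        acc[[key]] <<- ifelse(is.na(val), 0, val)
        nacc[[key]] <<- ok
      } else {
        acc[[key]] <<- acc[[key]] + ifelse(is.na(val), 0, val)
        nacc[[key]] <<- nacc[[key]] + ok
      }
    }
    events_by_ref <- setNames(vector("list", length(refs)), refs)
    for (si in seg_idx) {
      xm <- segment_signal(recording, segments$start[si],
                           segments$duration[si])
      xm <- xm[, refinfo[[1]]$input, drop = FALSE]
      xm <- filter_signal(xm, fs = fs)
      w0 <- if (need_welch)
        welch_spectra(xm, fs, config$window_s, config$overlap) else NULL
      bandm <- if (need_bandfilt)
        lapply(setNames(bands, bands), function(b)
          apply(xm, 2, band_filter, band = b, fs = fs)) else NULL
      for (ref in refs) {
        ri <- refinfo[[ref]]
        labs <- ri$labels
        nch <- length(labs)
        x <- xm %*% ri$A
        colnames(x) <- labs
        stft <- NULL
        if (need_welch) {
          stft <- array(matrix(w0$stft, ncol = dim(w0$stft)[3]) %*% ri$A,
                        dim = c(w0$nb, w0$n_windows, nch))
        }
        bandf <- if (need_bandfilt)
          lapply(bandm, function(mm) mm %*% ri$A) else NULL
        phasors <- if ("plv" %in% feats)
          lapply(bandf, function(mm)
            apply(mm, 2, function(v) exp(1i * analytic_phase(v)))) else NULL
        if (need_spk) {
          for (ch in seq_len(nch)) {
            ev <- detect_spikes(x[, ch], fs, config$detector)
            if (nrow(ev))
              events_by_ref[[ref]] <- rbind(
                events_by_ref[[ref]],
                data.frame(channel = labs[ch],
                           peak_s = ev$peak_s + segments$start[si],
                           amplitude = ev$amplitude, segment = si,
                           stringsAsFactors = FALSE))
          }
        }
        if ("ll" %in% feats)
          add(paste("ll__bb", ref, sep = "__"),
              apply(x, 2, line_length, fs = fs))
        if (need_welch) {
          psd <- psd_from_stft(stft, w0$scale)
          if ("se" %in% feats) {
            m <- band_mask(w0$freq, "bb")
            add(paste("se__bb", ref, sep = "__"),
                setNames(apply(psd[m, , drop = FALSE], 2,
                               spectral_entropy_from_psd), labs))
          }
          if ("bp" %in% feats) {
            df <- w0$freq[2] - w0$freq[1]
            for (b in bands)
              add(paste("bp", b, ref, sep = "__"),
                  setNames(colSums(psd[band_mask(w0$freq, b), ,
                                       drop = FALSE]) * df, labs))
          }
        }
        pairs <- pairsinfo[[ref]]
        if (need_pairs && !is.null(pairs)) {
          np <- ncol(pairs)
          pm <- function(vals) {
            M <- matrix(NA_real_, nch, nch, dimnames = list(labs, labs))
            for (p in seq_len(np)) {
              M[pairs[1, p], pairs[2, p]] <- vals[p]
              M[pairs[2, p], pairs[1, p]] <- vals[p]
            }
            M
          }
          if ("pearson" %in% feats)
            add(paste("pearson__bb", ref, sep = "__"),
                pm(vapply(seq_len(np), function(p)
                  pearson_sq(x[, pairs[1, p]], x[, pairs[2, p]]), 1)))
          if ("xcor" %in% feats)
            add(paste("xcor__bb", ref, sep = "__"),
                pm(vapply(seq_len(np), function(p)
                  cross_corr(x[, pairs[1, p]], x[, pairs[2, p]],
                             max_lag), 1)))
          if ("coh" %in% feats) {
            cohv <- vapply(seq_len(np), function(p)
              coherence_bands_from_stft(stft[, , pairs[1, p]],
                                        stft[, , pairs[2, p]],
                                        w0$freq, bands),
              numeric(length(bands)))
            for (bi in seq_along(bands))
              add(paste("coh", bands[bi], ref, sep = "__"),
                  pm(cohv[bi, ]))
          }
          if ("plv" %in% feats)
            for (b in bands)
              add(paste("plv", b, ref, sep = "__"),
                  pm(vapply(seq_len(np), function(p) {
                    Ei <- phasors[[b]][, pairs[1, p]]
                    Ej <- phasors[[b]][, pairs[2, p]]
                    n <- length(Ei)
                    if (n > 2 * plv_trim + 2) {
                      keep <- (plv_trim + 1):(n - plv_trim)
                      Ei <- Ei[keep]; Ej <- Ej[keep]
                    }
                    Mod(mean(Ei * Conj(Ej)))
                  }, 1)))
          if ("re" %in% feats)
            for (b in bands)
              add(paste("re", b, ref, sep = "__"),
                  pm(vapply(seq_len(np), function(p)
                    relative_entropy_hist(bandf[[b]][, pairs[1, p]],
                                          bandf[[b]][, pairs[2, p]],
                                          config$re_bins,
                                          config$re_smoothing), 1)))
        }
      }
    }
    # averages over contributing segments
    for (key in names(acc)) {
      cells[[paste(key, st, sep = "__")]] <-
        acc[[key]] / ifelse(nacc[[key]] > 0, nacc[[key]], NA)
    }
    # spike-derived cells from pooled events
    if (need_spk) {
      for (ref in refs) {
        labs <- refinfo[[ref]]$labels
        ev <- events_by_ref[[ref]] %||%
          data.frame(channel = character(0), peak_s = numeric(0),
                     segment = integer(0))
        if ("spikes" %in% feats) {
          r <- if (length(seg_idx))
            spike_rate(ev, segments, state_stage(st), labs)
          else setNames(rep(NA_real_, length(labs)), labs)
          cells[[paste("spikes", "bb", ref, st, sep = "__")]] <- r
        }
        if ("rl" %in% feats) {
          lat <- setNames(rep(NA_real_, length(labs)), labs)
          if (nrow(ev)) {
            seqs <- do.call(rbind, lapply(split(ev, ev$segment),
                                          group_sequences,
                                          gap_ms = config$gap_ms))
            lat <- recruitment_latency(seqs, labs)
          }
          cells[[paste("rl", "bb", ref, st, sep = "__")]] <- lat
        }
      }
    }
    # entirely-missing state: materialize NA cells
    if (!length(seg_idx)) {
      for (ref in refs) {
        labs <- refinfo[[ref]]$labels
        for (key in ai_feature_keys(feats, ref, st))
          if (is.null(cells[[key]]))
            cells[[key]] <- setNames(rep(NA_real_, length(labs)), labs)
      }
    }
  }
  structure(list(cells = cells,
                 side = lapply(refinfo, `[[`, "side"),
                 states_n = states_n, config = config,
                 keys = ai_feature_keys(feats, refs, states)),
            class = "feature_grid")
}

#' @export
print.feature_grid <- function(x, ...) {
  cat(sprintf("<feature_grid> %d cells (%d keys expected)\n",
              length(x$cells), length(x$keys)))
  invisible(x)
}
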