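#' Synthetic bilateral iEEG cohort configuration
#'
#' Defaults mirror a typical bilateral temporal implant cohort: 47 patients
#' with a 20/10/17 left/right/bilateral split, 12-hour records, three
#' temporal electrodes per side with 12 contacts each, interictal spike rates
#' of 10/min on the seizure-onset side versus 2.5/min contralaterally (4:1),
#' spikes at 8x the rolling background SD, a 30% intra-hemispheric
#' connectivity reduction on the onset side, and hour-long wake/N2-N3
#' alternation. Tests and examples pass smaller sizes explicitly.
#'
#' @param n_patients cohort size.
#' @param laterality_mix named proportions over left/right/bilateral
#'   (sum 1).
#' @param fs sampling rate, Hz (>= 200 so the 30--80 Hz band is resolvable).
#' @param duration_hours record length.
#' @param electrodes_per_side,contacts_per_electrode electrode geometry.
#' @param spike_rate_soz,spike_rate_contra spikes/min on the onset and
#'   contralateral sides (bilateral onset spikes at the SOZ rate on both).
#' @param spike_amplitude_sd_mult spike peak as a multiple of the channel's
#'   background SD.
#' @param connectivity_asymmetry fractional reduction of the intra-hemispheric
#'   shared-signal variance on the onset side, in `[0, 1)`.
#' @param sleep_cycle_minutes length of each wake / N2-N3 block (record
#'   starts awake).
#' @param p_correct probability a unilateral patient is operated on the true
#'   side.
#' @param outcome_noise probability the good/poor outcome label is flipped.
#' @param seed integer master seed.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(n_patients = 47,
                       laterality_mix = c(left = 20, right = 10,
                                          bilateral = 17) / 47,
                       fs = 256, duration_hours = 12,
                       electrodes_per_side = 3, contacts_per_electrode = 12,
                       spike_rate_soz = 10, spike_rate_contra = 2.5,
                       spike_amplitude_sd_mult = 8,
                       connectivity_asymmetry = 0.3,
                       sleep_cycle_minutes = 60,
                       p_correct = 0.8, outcome_noise = 0.1, seed = 1) {
  mix <- laterality_mix
  if (is.null(names(mix))) names(mix) <- c("left", "right", "bilateral")
  if (!setequal(names(mix), c("left", "right", "bilateral")))
    stop("laterality_mix must be named over left/right/bilateral")
  if (all(mix == 0)) stop("degenerate laterality mix (all zero)")
  if (abs(sum(mix) - 1) > 1e-9) stop("laterality_mix must sum to 1")
  if (any(mix < 0)) stop("negative mix proportion")
  if (fs < 200) stop("fs too low for 80 Hz content (need >= 200 Hz)")
  if (duration_hours <= 0) stop("zero-duration record")
  if (spike_rate_soz < 0 || spike_rate_contra < 0) stop("rates must be >= 0")
  if (connectivity_asymmetry < 0 || connectivity_asymmetry >= 1)
    stop("connectivity_asymmetry must be in [0, 1)")
  structure(list(
    n_patients = n_patients, laterality_mix = mix[c("left", "right",
                                                    "bilateral")],
    fs = fs, duration_hours = duration_hours,
    electrodes_per_side = electrodes_per_side,
    contacts_per_electrode = contacts_per_electrode,
    spike_rate_soz = spike_rate_soz, spike_rate_contra = spike_rate_contra,
    spike_amplitude_sd_mult = spike_amplitude_sd_mult,
    connectivity_asymmetry = connectivity_asymmetry,
    sleep_cycle_minutes = sleep_cycle_minutes,
    p_correct = p_correct, outcome_noise = outcome_noise, seed = seed),
    class = "sim_config")
}

# 1/f-shaped ("pink") unit-variance noise: white noise through the standard
# 3-pole pinking filter (Kellet), then rescaled
pink_noise <- function(n) {
  b <- c(0.049922035, -0.095993537, 0.050612699, -0.004408786)
  a <- c(1, -2.494956002, 2.017265875, -0.522189400)
  x <- iir_filter(b, a, rnorm(n))
  x / sd(x)
}

# unit-variance narrowband noise centred on f0 (2nd-order Butterworth
# bandpass of white noise); rhythms are stochastic, not deterministic tones,
# so common-average subtraction cannot cancel them by chance phase alignment
narrowband_noise <- function(n, fs, f0, bw) {
  f <- cached_butter(2, c(f0 - bw, f0 + bw) / (fs / 2), "pass")
  x <- iir_filter(f$b, f$a, rnorm(n))
  x / sd(x)
}

# stereotyped spike: biphasic sharp transient (70 ms) + slow wave (300 ms),
# unit peak amplitude
spike_waveform <- function(fs, sharp_ms = 70, slow_ms = 300,
                           slow_frac = 0.4) {
  n1 <- round(sharp_ms * 4 / 7 / 1000 * fs)   # 40 ms positive phase
  n2 <- round(sharp_ms * 3 / 7 / 1000 * fs)   # 30 ms negative phase
  n3 <- round(slow_ms / 1000 * fs)
  c(sin(pi * seq_len(n1) / (n1 + 1)),
    -0.6 * sin(pi * seq_len(n2) / (n2 + 1)),
    slow_frac * sin(pi * seq_len(n3) / (n3 + 1)))
}

# wake(1)/sleep(gain) square wave over the record, starting awake
sleep_gain <- function(n, fs, cycle_minutes, gain) {
  block <- floor((seq_len(n) - 1) / fs / (cycle_minutes * 60))
  ifelse(block %% 2 == 0, 1, gain)
}

sleep_blocks <- function(duration_s, cycle_minutes) {
  # (start, end, stage) table of the generator's simulated stages
  cl <- cycle_minutes * 60
  starts <- seq(0, duration_s - 1e-9, by = cl)
  data.frame(start = starts, end = pmin(starts + cl, duration_s),
             stage = ifelse(seq_along(starts) %% 2 == 1, "W", "N2"))
}

#' Ground-truth record for one synthetic patient
#'
#' @param patient_id identifier.
#' @param true_laterality `"left"`, `"right"` or `"bilateral"`.
#' @param surgery_side `"left"`, `"right"` or `"none"`.
#' @param outcome_good logical or `NA` (undefined when unoperated).
#' @param engel,ilae one-year outcome scores (`NA` when unoperated).
#' @param seed per-patient generation seed.
#' @return a `ground_truth` list.
#' @export
ground_truth <- function(patient_id, true_laterality,
                         surgery_side = "none", outcome_good = NA,
                         engel = NA_real_, ilae = NA_real_, seed = 1) {
  stopifnot(true_laterality %in% c("left", "right", "bilateral"),
            surgery_side %in% c("left", "right", "none"))
  if (surgery_side == "none" && isTRUE(!is.na(outcome_good)))
    stop("outcome undefined without surgery")
  structure(list(patient_id = patient_id, true_laterality = true_laterality,
                 surgery_side = surgery_side, outcome_good = outcome_good,
                 engel = engel, ilae = ilae, seed = seed,
                 injected_spike_times = NULL),
            class = "ground_truth")
}

#' Generate one synthetic bilateral iEEG recording
#'
#' Per channel: background = an intra-hemispheric shared 1/f + white process
#' (shared-variance fraction 0.4, reduced by `connectivity_asymmetry` on the
#' seizure-onset side) plus per-channel delta (2 Hz) and alpha (10 Hz)
#' oscillations, with the delta amplitude gained x6 during simulated N2/N3
#' blocks; interictal spikes are injected as homogeneous per-channel Poisson
#' events (SOZ-side rate on the onset hemisphere(s)) using a stereotyped
#' sharp-plus-slow-wave waveform scaled to `spike_amplitude_sd_mult` times
#' the channel's background SD. Identical seeds give identical records.
#'
#' @param config a [sim_config()].
#' @param truth a [ground_truth()]; its `seed` drives the channel noise and
#'   spike draws.
#' @return an `ieeg_recording` whose `injected_spikes` attribute holds the
#'   per-channel injected peak times (seconds); the returned truth (attribute
#'   `truth`) has `injected_spike_times` filled.
#' @export
generate_recording <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"), inherits(truth, "ground_truth"))
  fs <- config$fs
  n <- round(config$duration_hours * 3600 * fs)
  if (n < 1) stop("zero-duration record")
  dur_s <- n / fs
  sides <- c("L", "R")
  elecs <- LETTERS[seq_len(config$electrodes_per_side)]
  labels <- as.vector(t(outer(
    as.vector(outer(sides, elecs, paste0)),
    seq_len(config$contacts_per_electrode), paste0)))
  lab_side <- substr(labels, 1, 1)
  soz_sides <- switch(truth$true_laterality,
                      left = "L", right = "R", bilateral = c("L", "R"))
  c0 <- 0.4
  sd_bg <- 20; amp_delta <- 5; amp_alpha <- 10; gain_sleep <- 6
  with_seed(truth$seed, {
    gain <- sleep_gain(n, fs, config$sleep_cycle_minutes, gain_sleep)
    shared <- list(
      L = sqrt(0.5) * pink_noise(n) + sqrt(0.5) * rnorm(n),
      R = sqrt(0.5) * pink_noise(n) + sqrt(0.5) * rnorm(n))
    x <- matrix(0, length(labels), n)
    spike_times <- setNames(vector("list", length(labels)), labels)
    wf <- spike_waveform(fs)
    peak_off <- which.max(wf) - 1L           # samples from onset to peak
    for (ch in seq_along(labels)) {
      s <- lab_side[ch]
      cc <- if (s %in% soz_sides) c0 * (1 - config$connectivity_asymmetry)
            else c0
      priv <- sqrt(0.5) * pink_noise(n) + sqrt(0.5) * rnorm(n)
      bg <- sd_bg * (sqrt(cc) * shared[[s]] + sqrt(1 - cc) * priv)
      # delta/alpha rhythms: narrowband noise at the sinusoid-equivalent SD
      bg <- bg + (amp_delta / sqrt(2)) * gain *
        narrowband_noise(n, fs, 2, 0.5)
      bg <- bg + (amp_alpha / sqrt(2)) * narrowband_noise(n, fs, 10, 1)
      rate <- if (s %in% soz_sides) config$spike_rate_soz
              else config$spike_rate_contra
      n_sp <- rpois(1, rate * dur_s / 60)
      amp <- config$spike_amplitude_sd_mult * sd(bg)
      if (n_sp > 0) {
        pk <- sort(runif(n_sp, 1, dur_s - 1))
        for (p in pk) {
          i0 <- round(p * fs) - peak_off
          ix <- i0 + seq_along(wf) - 1L
          keep <- ix >= 1 & ix <= n
          bg[ix[keep]] <- bg[ix[keep]] + amp * wf[keep]
        }
        spike_times[[ch]] <- pk
      } else spike_times[[ch]] <- numeric(0)
      x[ch, ] <- bg
    }
    rec <- new_recording(x, fs, labels)
    truth$injected_spike_times <- spike_times
    attr(rec, "injected_spikes") <- spike_times
    attr(rec, "truth") <- truth
    attr(rec, "sleep_blocks") <- sleep_blocks(dur_s,
                                              config$sleep_cycle_minutes)
    rec
  })
}

#' Generate a synthetic cohort with clinical ground truth
#'
#' Lateralities are drawn from `laterality_mix`. Unilateral patients undergo
#' surgery on the true side with probability `p_correct` (otherwise the
#' opposite side); bilateral patients are unoperated (`surgery_side`
#' `"none"`). The latent good outcome is `surgery side == true laterality`,
#' flipped with probability `outcome_noise`; good outcomes score Engel 1 /
#' ILAE 1--2 at one year, poor outcomes Engel 2--4 / ILAE 3--5.
#'
#' @param config a [sim_config()].
#' @param materialize if `TRUE`, generate all recordings now (memory-heavy
#'   for large configs); if `FALSE`, return truths only and generate
#'   recordings on demand via [generate_recording()].
#' @return list with `truths` (list of `ground_truth`), `config`, and (when
#'   materialized) `recordings`.
#' @export
generate_cohort <- function(config, materialize = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_patients < 1) stop("n_patients must be >= 1")
  with_seed(config$seed, {
    lat <- sample(names(config$laterality_mix), config$n_patients,
                  replace = TRUE, prob = config$laterality_mix)
    seeds <- sample.int(.Machine$integer.max - 1L, config$n_patients)
    truths <- vector("list", config$n_patients)
    for (i in seq_len(config$n_patients)) {
      if (lat[i] == "bilateral") {
        side <- "none"; good <- NA; engel <- NA_real_; ilae <- NA_real_
      } else {
        side <- if (runif(1) < config$p_correct) lat[i]
                else setdiff(c("left", "right"), lat[i])
        good <- side == lat[i]
        if (runif(1) < config$outcome_noise) good <- !good
        engel <- if (good) 1 else sample(2:4, 1)
        ilae <- if (good) sample(1:2, 1) else sample(3:5, 1)
      }
      truths[[i]] <- ground_truth(sprintf("sim%03d", i), lat[i], side, good,
                                  engel, ilae, seed = seeds[i])
    }
    out <- list(truths = truths, config = config)
    if (materialize) {
      out$recordings <- lapply(truths, function(tr)
        generate_recording(config, tr))
      for (i in seq_along(truths))
        out$truths[[i]] <- attr(out$recordings[[i]], "truth")
    }
    class(out) <- "sim_cohort"
    out
  })
}

#' @export
print.sim_cohort <- function(x, ...) {
  lat <- vapply(x$truths, `[[`, "", "true_laterality")
  cat(sprintf("<sim_cohort> %d patients (%s)\n", length(x$truths),
              paste(names(table(lat)), table(lat), sep = "=",
                    collapse = ", ")))
  invisible(x)
}

#' Generate parcel-averaged BOLD series with a lateralized factor structure
#'
#' Each hemisphere's parcels load on a hemisphere-shared latent factor
#' (loading `base_loading`), giving intra-side parcel correlations of about
#' the loading squared; on the seizure-onset side(s) the loading is reduced
#' by the factor `1 - asymmetry`.
#'
#' @param n_patients number of subjects.
#' @param parcels_per_side temporal parcels per hemisphere (>= 2).
#' @param n_timepoints BOLD samples (>= 10).
#' @param asymmetry fractional loading reduction on the onset side.
#' @param seed integer seed.
#' @param laterality_mix named proportions over left/right/bilateral.
#' @param base_loading factor loading on the unaffected side.
#' @return list with `series` (list of timepoints x parcels matrices),
#'   `parcel_side` (character vector), `laterality` (per subject).
#' @export
generate_parcel_bold <- function(n_patients, parcels_per_side = 10,
                                 n_timepoints = 200, asymmetry = 0.5,
                                 seed = 1,
                                 laterality_mix = c(left = 30, right = 17,
                                                    bilateral = 15) / 62,
                                 base_loading = 0.7) {
  if (parcels_per_side < 2) stop("need >= 2 parcels per side")
  if (n_timepoints < 10) stop("need >= 10 timepoints")
  with_seed(seed, {
    lat <- sample(names(laterality_mix), n_patients, replace = TRUE,
                  prob = laterality_mix)
    parcel_side <- rep(c("L", "R"), each = parcels_per_side)
    series <- lapply(seq_len(n_patients), function(i) {
      soz <- switch(lat[i], left = "L", right = "R",
                    bilateral = c("L", "R"))
      out <- matrix(0, n_timepoints, 2 * parcels_per_side)
      for (s in c("L", "R")) {
        lam <- if (s %in% soz) base_loading * (1 - asymmetry)
               else base_loading
        f <- rnorm(n_timepoints)
        ix <- which(parcel_side == s)
        for (p in ix)
          out[, p] <- lam * f + sqrt(1 - lam^2) * rnorm(n_timepoints)
      }
      colnames(out) <- paste0(parcel_side, ".", seq_len(parcels_per_side))
      out
    })
    list(series = series, parcel_side = parcel_side, laterality = lat)
  })
}
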