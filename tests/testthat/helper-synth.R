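# Small synthetic-cohort builders shared across tests. Heavy cohorts are
# cached per configuration key so acceptance checks can share them.

.test_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.test_cache[[key]])) .test_cache[[key]] <- force(expr)
  .test_cache[[key]]
}

# minimal spike-AI study config: 20-min records, 2 contacts/side
spike_study_config <- function(n = 60, seed = 1, ...) {
  args <- utils::modifyList(
    list(n_patients = n, fs = 200, duration_hours = 1 / 3,
         electrodes_per_side = 1, contacts_per_electrode = 2,
         sleep_cycle_minutes = 10, seed = seed),
    list(...))
  do.call(sim_config, args)
}

# grid study config: 8 channels so every reference has intra-side pairs
grid_study_config <- function(n = 1, seed = 1, ...) {
  args <- utils::modifyList(
    list(n_patients = n, fs = 200, duration_hours = 1 / 3,
         electrodes_per_side = 2, contacts_per_electrode = 2,
         sleep_cycle_minutes = 10, seed = seed),
    list(...))
  do.call(sim_config, args)
}

spike_ai_dataset <- function(n = 60, seed = 1, ...) {
  key <- paste("spike_ds", n, seed, paste(c(...), collapse = "_"))
  cached(key, {
    coh <- generate_cohort(spike_study_config(n, seed, ...),
                           materialize = FALSE)
    cohort_spike_ai(coh, seed = seed * 1000 + 7)
  })
}

small_recording <- function(seed = 11, laterality = "left",
                            config = grid_study_config(seed = 1)) {
  generate_recording(config, ground_truth("pt", laterality, seed = seed))
}

# relabel hemispheres L <-> R on a recording (data untouched)
swap_hemispheres <- function(recording) {
  sw <- chartr("LR", "RL", recording$labels)
  recording$labels <- sw
  rownames(recording$samples) <- sw
  recording
}

# deterministic montage helper for label-level tests
simple_montage <- function(labels, temporal = NULL) {
  select_symmetric_temporal(parse_channel_labels(labels, temporal))
}
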