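test_that("configuration invariants are enforced", {
  expect_error(sim_config(laterality_mix = c(left = 0, right = 0,
                                             bilateral = 0)), "degenerate")
  expect_error(sim_config(laterality_mix = c(left = 0.5, right = 0.4,
                                             bilateral = 0.2)), "sum to 1")
  expect_error(sim_config(fs = 128), "80 Hz")
  expect_error(sim_config(duration_hours = 0), "duration")
  expect_error(sim_config(spike_rate_soz = -1), ">= 0")
  expect_error(sim_config(connectivity_asymmetry = 1), "\\[0, 1\\)")
})

test_that("identical seeds give bit-identical recordings and cohorts", {
  cfg <- spike_study_config(n = 3, seed = 9)
  tr <- ground_truth("p", "right", seed = 33)
  r1 <- generate_recording(cfg, tr)
  r2 <- generate_recording(cfg, tr)
  expect_identical(r1$samples, r2$samples)
  expect_identical(attr(r1, "injected_spikes"), attr(r2, "injected_spikes"))
  c1 <- generate_cohort(cfg, materialize = FALSE)
  c2 <- generate_cohort(cfg, materialize = FALSE)
  expect_identical(c1$truths, c2$truths)
})

test_that("spike injection matches laterality and conserves its bookkeeping", {
  cfg <- spike_study_config(n = 1, seed = 10, spike_rate_soz = 10,
                            spike_rate_contra = 1)
  rec <- generate_recording(cfg, ground_truth("p", "left", seed = 5))
  inj <- attr(rec, "injected_spikes")
  side <- substr(names(inj), 1, 1)
  nl <- sum(lengths(inj[side == "L"]))
  nr <- sum(lengths(inj[side == "R"]))
  # 10:1 rate ratio within Poisson error (counts ~ Poisson(rate * minutes))
  expect_gt(nl, nr * 4)
  mins <- recording_duration(rec) / 60
  expect_lt(abs(nl - 10 * mins * sum(side == "L")) /
              sqrt(10 * mins * sum(side == "L")), 4)
  # conservation: truth records exactly the injected event lists
  truth <- attr(rec, "truth")
  expect_identical(truth$injected_spike_times, inj)
  expect_true(all(unlist(inj) > 0 & unlist(inj) < recording_duration(rec)))
  # bilateral: both sides spike at the SOZ rate
  recb <- generate_recording(cfg, ground_truth("p", "bilateral", seed = 6))
  injb <- attr(recb, "injected_spikes")
  expect_gt(sum(lengths(injb[side == "R"])), nr * 3)
})

test_that("cohort assembly follows the mix and outcome rule", {
  cfg <- spike_study_config(n = 40, seed = 11,
                            laterality_mix = c(left = 1, right = 0,
                                               bilateral = 0))
  coh <- generate_cohort(cfg, materialize = FALSE)
  expect_true(all(vapply(coh$truths, `[[`, "", "true_laterality") ==
                    "left"))
  # p_correct = 1, no noise: every operated patient has a good outcome
  cfg2 <- spike_study_config(n = 30, seed = 12, p_correct = 1,
                             outcome_noise = 0)
  coh2 <- generate_cohort(cfg2, materialize = FALSE)
  op <- Filter(function(t) t$surgery_side != "none", coh2$truths)
  expect_true(length(op) > 0)
  expect_true(all(vapply(op, `[[`, TRUE, "outcome_good")))
  expect_true(all(vapply(op, `[[`, 1, "engel") == 1))
  # bilateral patients are unoperated with undefined outcome
  bil <- Filter(function(t) t$true_laterality == "bilateral", coh2$truths)
  expect_true(all(vapply(bil, `[[`, "", "surgery_side") == "none"))
  expect_true(all(is.na(vapply(bil, `[[`, NA, "outcome_good"))))
  # reproducible group counts under a fixed seed
  cfg3 <- spike_study_config(n = 60, seed = 13,
                             laterality_mix = c(left = 1, right = 1,
                                                bilateral = 1) / 3)
  lat <- vapply(generate_cohort(cfg3, FALSE)$truths, `[[`, "",
                "true_laterality")
  tab <- table(lat)
  expect_true(all(tab >= 10))            # multinomial(60, 1/3) plausibility
  expect_identical(as.vector(tab),
                   as.vector(table(vapply(
                     generate_cohort(cfg3, FALSE)$truths, `[[`, "",
                     "true_laterality"))))
})

test_that("connectivity is reduced on the seizure-onset side", {
  cfg <- spike_study_config(n = 1, seed = 14, connectivity_asymmetry = 0.7,
                            spike_rate_soz = 0, spike_rate_contra = 0)
  cfg$contacts_per_electrode <- 4
  rec <- generate_recording(cfg, ground_truth("p", "left", seed = 15))
  x <- t(rec$samples)
  side <- substr(rec$labels, 1, 1)
  mean_r <- function(s) {
    C <- cor(x[, side == s])
    mean(C[upper.tri(C)])
  }
  expect_lt(mean_r("L"), mean_r("R"))
})

test_that("exchangeable generators produce AI centred on zero", {
  # symmetric rates and no connectivity asymmetry: spike-rate AI ~ 0
  ais <- vapply(1:8, function(s) {
    cfg <- spike_study_config(n = 1, seed = s + 100,
                              spike_rate_soz = 10, spike_rate_contra = 10,
                              connectivity_asymmetry = 0)
    rec <- generate_recording(cfg, ground_truth("p", "left",
                                                seed = s + 200))
    cm <- sleep_spike_counts(rec, seed = s)
    side <- attr(cm, "side")
    rates <- rowSums(cm) / max(1, ncol(cm))
    asymmetry_index(mean(rates[side == "L"]), mean(rates[side == "R"]))
  }, 1)
  expect_lt(abs(mean(ais)), 0.15)
})
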