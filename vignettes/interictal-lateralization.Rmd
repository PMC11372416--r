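---
title: "Lateralizing temporal lobe epilepsy from interictal iEEG asymmetry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lateralizing temporal lobe epilepsy from interictal iEEG asymmetry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(interlat)
```

## The clinical problem

Patients with drug-resistant temporal lobe epilepsy (TLE) often undergo
intracranial EEG (iEEG) with bilateral temporal electrodes so clinicians can
watch several seizures and decide whether the seizure onset zone (SOZ) is
left-sided, right-sided or bilateral. Seizures are rare and waiting for them
is costly; the *interictal* record — everything between seizures — is
abundant but underused. This package implements a quantitative pipeline that
turns interictal iEEG into a lateralization estimate: extract per-contact
features, collapse them into left–right asymmetry indices, and classify
laterality with a penalized regression model validated out-of-sample.

## The asymmetry index

Every feature is summarized per hemisphere and collapsed to

$$AI = \frac{F_{left} - F_{right}}{F_{left} + F_{right}},$$

where $F_{left}$ is the mean of the feature over retained left temporal
contacts (for connectivity features, over intra-left contact pairs).
Positive AI means left-dominant. The statistic is only meaningful for
non-negative features, so band power enters on the raw power scale, never in
dB; a degenerate denominator ($|F_L+F_R| < 10^{-12}$) yields a missing
value. Because channels are restricted to symmetric bilateral pairs, the AI
of any hemispherically exchangeable process is antisymmetric under
relabelling — the package's central invariant, tested exactly (to the last
bit) on synthetic cohorts.

## Conditioning pipeline

1. **Montage parsing.** Labels follow the stereo-EEG grammar (leading L/R,
   trailing contact number); a metadata table can override the
   temporal-lobe flag per contact. Unparseable channels (e.g. `EKG`) are
   never analysed.
2. **Artifact channels.** A channel is dropped when its median absolute
   deviation exceeds 10x the cross-channel median, when 60 Hz carries more
   than half its 0.5–80 Hz power, or when it is flat. These thresholds are
   config arguments; the reference method they stand in for is a manual
   review, so defaults are deliberately conservative.
3. **Symmetric selection.** Only temporal contacts whose mirror-image
   contact is present and clean are retained, guaranteeing equal left and
   right channel counts and removing the inter-contact-distance confound
   from connectivity comparisons.
4. **Referencing.** Machine (as recorded), common average (over the
   retained set), and bipolar (adjacent contacts on one electrode) —
   all linear maps of the retained channels, applied after contact
   selection.
5. **Filtering.** Zero-phase 60 Hz notch (biquad, Q = 30) and 0.5–80 Hz
   Butterworth bandpass (2nd-order high-pass and low-pass sections in
   cascade). Zero-phase (forward–backward) application avoids skewing spike
   timing; the cascade form keeps the 0.5 Hz edge numerically stable at
   clinical sampling rates.
6. **Segmentation.** The record is cut into 10-minute parents and one
   1-minute segment is drawn per parent at a uniform integer-second offset
   (a 12-hour record gives exactly 72 segments). Segments overlapping
   annotated seizures are excluded and *not* re-drawn — the conservative
   choice when the original procedure is unstated.
7. **Sleep staging.** External per-epoch labels are used when available
   (W maps to wake; N2/N3 to the sleep state; N1/REM/transitions to
   `other`, analysed in neither state). Otherwise a delta-power proxy
   stager labels a segment sleep when relative delta power
   (0.5–4 Hz over 0.5–80 Hz, common-average montage) is at least 0.5 and
   wake when at most 0.3. The two thresholds are configuration defaults
   sized so the synthetic generator's states sit well clear of both (see
   below); they are a proxy, not a reimplementation of a validated stager.

## Features

Ten features are computed per segment and averaged within each (reference,
state): line length, band power, spike rate, spike recruitment latency,
spectral entropy (univariate); squared Pearson correlation, maximal lagged
cross-correlation, magnitude-squared coherence, phase-locking value and
relative entropy (bivariate, intra-hemispheric pairs only). Band-resolved
features (band power, coherence, PLV, relative entropy) are evaluated on
broadband (0.5–80 Hz) plus delta/theta/alpha/beta/gamma
(0.5–4/4–8/8–12/12–30/30–80 Hz); the remainder are broadband-only. With
three references and two states this enumerates
$(6 + 4\times6)\times3\times2 = 180$ AI features, keyed
`feature__band__reference__state`.

Numerical choices, all config-exposed: Welch spectra use 2-s Hann windows
with 50 % overlap (0.5 Hz resolution inside a 1-minute segment);
cross-correlation scans lags up to 200 ms with exact per-lag Pearson
normalization; relative entropy is the symmetrized Kullback–Leibler
divergence between 30-bin amplitude histograms on the pooled range with
$10^{-6}$ additive smoothing (band-filtered amplitude histograms — the
spectral alternative is a documented open choice); PLV discards 0.5 s of
analytic phase at each segment edge to suppress filter transients. Spike
detection is a deterministic amplitude/slope/duration detector (5x rolling
MAD amplitude, 3x robust slope, 20–200 ms sharp width, 200 ms refractory)
standing in for a validated published detector that is outside this
package's scope; pre-computed spike tables in the same schema can be
substituted. Sequences are single-linkage chains with a 100 ms gap, the
first spike of a sequence having latency 0 ms; per-channel recruitment
latency is the mean latency over the sequences the channel joins (the
summary statistic is unstated upstream; the mean is our documented choice).

## Laterality models

Two one-versus-rest classifiers are fitted: left versus right-or-bilateral
and right versus left-or-bilateral. The pipeline per fit: median imputation
of missing AIs (training medians only — the apply set never contributes),
z-scoring by training mean/SD (standardizing before PCA is implied rather
than stated upstream; we standardize), PCA retaining the smallest component
set explaining 95 % of training variance, then L1-penalized logistic
regression on the scores with $\lambda = 1/N$ and inverse-class-frequency
observation weights. The solver is an IRLS coordinate-descent with
tolerance $10^{-8}$, chosen for bit-reproducibility; its solutions are
checked in the tests against an independent proximal-gradient reference.
Internal validation is leave-one-patient-out with the entire pipeline refit
per fold; pooled held-out probabilities give the ROC, the AUC
(Mann–Whitney), and the operating point maximizing Youden's J (ties broken
toward the lower threshold). External cohorts are scored by the frozen
pipeline at the internal threshold. Feature importance maps the
coefficients back through the PCA loadings. Raw logistic outputs are
reported without recalibration. A spike-only model (sleep, common-average
reference) and its binarized variant (1 if the spike AI is positive, 0
otherwise; exactly 0 codes as 0 with a warning) mirror a clinician's
"which side spikes more" heuristic, and a calculator entry point maps a
pair of left/right sleep spike rates to the AI and both model
probabilities.

## Outcome analyses

For each operated patient the model matching the surgery side supplies a
"concordant" probability; good outcome is Engel 1 (or ILAE 1–2) at one
year. Group statistics use pooled-variance t-tests with Cohen's d, one-way
ANOVA with $\eta^2$, Benjamini–Hochberg control at 0.05, and Fisher's exact
test for 2x2 association tables; a single-predictor logistic model of good
outcome on the concordant probability is validated leave-one-out.
Missing AIs are dropped pairwise per feature, so per-analysis n varies.

## The synthetic cohort generator

Because the source data are protected patient recordings, the package
ships a seeded generator whose statistical structure carries known ground
truth: symmetric bilateral temporal montages; background per channel of
half pink (IIR-pinked) and half white noise at 20 uV SD, with an
intra-hemispheric shared fraction of 0.4 reduced by the configured
connectivity asymmetry on the onset side(s); stochastic narrowband delta
(2 ± 0.5 Hz) and alpha (10 ± 1 Hz) rhythms at 5/sqrt(2) and 10/sqrt(2) uV
SD, the delta gained 6x during sleep blocks (square-wave wake/N2–N3
alternation, record starting awake); and per-channel homogeneous Poisson
interictal spikes — a 70 ms biphasic sharp transient plus 300 ms slow wave
scaled to 8x the channel's background SD — at 10/min on the onset side(s)
versus 2.5/min contralaterally (the 4:1 study ratio). Cohort defaults
mirror the modelled clinical population (47 patients split 20/10/17
left/right/bilateral; 12-hour records; three 12-contact electrodes per
side). Unilateral patients are operated on the true side with probability
0.8 (otherwise the opposite side); the latent good outcome is "surgery side
equals truth", flipped with 10 % label noise; bilateral patients receive no
resective surgery. The oscillation SDs were sized by closed-form arithmetic
so the generator's sleep and wake delta ratios (about 0.60 and 0.22 after
common-average referencing) sit comfortably on either side of the proxy
stager thresholds. The rhythms are *narrowband noise*, not deterministic
sinusoids: with a small montage, a common sinusoid can be cancelled almost
exactly by the common average when per-channel phases happen to align,
which is an artifact of an over-idealized simulation rather than a property
of sleep EEG.

What the generator does *not* emulate: propagating multi-channel spike
sequences (spikes are independent per channel, so recruitment-latency AIs
are centred on zero), ictal or peri-ictal activity, non-stationary
spike-rate cycles, realistic sleep architecture beyond the square wave, and
inter-site heterogeneity. Tests passing on this generator therefore
demonstrate the pipeline's correctness and its ability to recover injected
asymmetries — not clinical performance on real iEEG.

## Problem sizes used by the tests and the acceptance script

All end-to-end checks run on scaled cohorts chosen as this package's own
study sizes: spike-model cohorts of n = 60 patients with 20-minute
records and two contacts per side (five seeds; a pooled n = 300
permutation null); the hemisphere-swap suite on twenty 8-channel patients;
the duration-subsampling cohort of n = 30 with 3-hour records (eight
sleep minutes per patient, compared at five sampled minutes versus the full
set); and a 62-subject parcel-BOLD cohort for the fMRI asymmetry analogue.
A 12-hour single-pair record exercises the segmentation count.

## Known limitations

The spike detector and sleep stager are documented stand-ins; absolute
detector sensitivity on real data is unknown (the modelled upstream
validation covered positive predictive value only). The AI presumes
non-negative features and symmetric coverage; montages without a single
clean symmetric temporal pair are rejected rather than approximated.
Duration subsampling draws random minutes without replacement — contiguous
subsampling is not implemented. EDF support covers plain continuous 16-bit
records (no annotations, one sampling rate).
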