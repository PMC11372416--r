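Package: interlat
Title: Lateralizing Temporal Lobe Epilepsy from Interictal Intracranial EEG Asymmetry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools to lateralize the seizure onset zone in temporal lobe
    epilepsy from interictal (between-seizure) intracranial EEG. Implements
    channel montage parsing and symmetric temporal-contact selection, artifact
    channel rejection, machine/common-average/bipolar referencing, zero-phase
    filtering, random one-minute segmentation with sleep/wake staging, an
    interictal spike detector with sequence grouping and recruitment latency,
    a grid of univariate and bivariate (connectivity) features across canonical
    frequency bands, left-right asymmetry indices, PCA + LASSO logistic
    classifiers of seizure onset laterality with leave-one-patient-out
    cross-validation and external validation, surgical outcome concordance
    statistics, and a seeded synthetic bilateral iEEG cohort generator with
    known ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
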