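Package: gliocircuit
Title: Electrophysiology and Statistics for Glioma Neural-Circuit Remodelling Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tested pipeline for the electrophysiological and statistical
    procedures used to characterise functional remodelling of neural circuits
    by high-grade glioma: speech-locked high-gamma band power and
    event-related spectral perturbations from electrocorticography with
    kurtosis-based channel screening and tumour-contact labelling;
    leave-one-participant-out decoding of word-frequency conditions;
    voxel-level imaginary-coherence functional connectivity with
    contralesional-referenced testing and tertile
    high/low-functional-connectivity classification; multitaper spectral
    estimation with Lorentzian aperiodic correction and aperiodic-corrected
    gamma power; multi-electrode-array spike, burst, network-burst and
    cross-correlogram synchrony metrics; and the supporting clinical
    statistics (mixed-effects tissue contrasts, false-discovery-rate
    adjustment, extent of resection, Kaplan-Meier and log-rank summaries).
    Every input class can be simulated by seeded generators that record
    ground truth alongside the data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    lme4,
    lmerTest,
    minpack.lm,
    Rcpp,
    RNifti,
    signal,
    stats,
    survival,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
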