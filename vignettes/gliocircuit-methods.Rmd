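---
title: "Methods: electrophysiology and statistics for glioma neural-circuit analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: electrophysiology and statistics for glioma neural-circuit analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

High-grade gliomas do not sit passively inside cortex: they integrate into
the surrounding neural circuitry, raise local excitability, and remodel the
functional connectivity between the tumour-infiltrated region and the rest
of the brain. Characterising that remodelling requires a heterogeneous set
of measurements — intraoperative electrocorticography (ECoG) during speech
tasks, resting-state magnetoencephalography (MEG) source maps,
multi-electrode-array (MEA) recordings of neuron–glioma co-cultures, and
clinical survival statistics. `gliocircuit` implements that analysis chain
as a single tested package, together with seeded simulators for every input
class so that each stage can be validated against known ground truth.

This vignette documents the models, the parameters that matter, the
numerical choices, and what the synthetic benchmarks do and do not show
about real data.

## Speech-locked high-gamma analysis (ECoG)

High-gamma band power (HGp, 70–110 Hz) tracks local population spiking and
rises in tumour-infiltrated cortex during speech production. The processing
chain is:

1. **Channel screening.** Channels whose sample kurtosis (Pearson
   convention, Gaussian = 3) exceeds 5.0 are rejected as artifactual;
   zero-variance channels are rejected with a distinct `degenerate` reason
   because kurtosis is undefined for them. Screening happens before
   referencing, so the common average is computed over retained channels
   only.
2. **Trial screening.** Trials with an incorrect response or a
   stimulus-to-response latency strictly greater than 2 s are discarded; a
   latency of exactly 2.0 s is kept.
3. **Epoching.** Windows of ±2,000 ms around speech onset, half-open
   `[-2, +2)` s, so an epoch holds exactly `4 × fs` samples with onset at
   0-based index `2 × fs`. Trials whose window crosses a recording edge are
   dropped and logged.
4. **HGp.** Common-average reference → 0.1 Hz high-pass → 70–110 Hz FIR
   band-pass (300 designed taps) → squared magnitude of the analytic
   signal. "Squared Hilbert transform" is read as the squared envelope of
   the analytic signal: it is the standard high-gamma power estimator and
   the only reading that yields nonnegative power. All FIR filters are
   applied forward–backward (zero phase) so that speech-locked latencies
   are not distorted; the stated order refers to the designed taps before
   bidirectional application.
5. **ERSP.** On the continuous recording: downsample to 600 Hz → 0.1 Hz
   high-pass → notch at 60 Hz and harmonics up to the post-downsample
   Nyquist → 70–170 Hz Hamming-windowed sinc FIR → analytic-signal envelope
   → 100 ms Gaussian smoothing (the 100 ms is taken as the kernel FWHM,
   sd ≈ 42.5 ms) → downsample to 100 Hz → per-trial, per-channel z-scoring.
   Zero-variance trials are flagged degenerate and excluded from z-scoring.

Tumour contacts are electrodes within 10 mm (inclusive at exactly 10.0 mm)
Euclidean distance of the necrotic tumour core geometry.

The group contrast (tumour vs normal-appearing channels) is fitted by the
statistics module's mixed model over all channels; the pair-matching of
individual electrode pairs used in some single-figure analyses is not
algorithmically specified anywhere we could ground it, so it is deliberately
not reimplemented.

## Word-frequency decoding

Low- versus high-frequency word trials are decoded from high-gamma envelope
features with an l2-regularised logistic regression classifier ("cost" 1,
read as the inverse regularisation strength C = 1) under
leave-one-participant-out cross-validation. Features are standardised per
fold with training-fold statistics only. The default feature window is
[−0.5, +0.5] s around onset at the 100 Hz ERSP rate — the window is not
pinned down by the source description, so it is configurable
(`decoding.window_s`). Significance is the exact binomial upper tail
P(X ≥ n_correct) at chance 0.5 (primary), with the one-sided normal Z-test
also reported. The ridge solve uses `glmnet` with
`lambda = 1/(n_train × cost)`, which reproduces the C-parameterised
objective.

The printed patient accuracies (0.56 in normal-appearing, 0.49 in
tumour-infiltrated cortex) require the patient recordings and are not
reproduction targets; the package reproduces the contrast qualitatively on
synthetic data.

## Imaginary-coherence connectivity mapping (MEG source space)

Voxel time series on an 8-mm grid are band-passed to alpha (8–12 Hz) and
segmented into 1 s Hann windows with 50% overlap (the spectral estimator is
not stated in the source; Welch averaging is the standard choice). For each
voxel pair the coherency `C_xy(f) = S_xy / sqrt(S_xx S_yy)` is formed from
the segment-averaged cross-spectra and the imaginary coherence
`IC = |Im C_xy|` is averaged over the band. Because any instantaneous real
mixing of sources has a purely real cross-spectrum, IC is insensitive to
volume conduction — appending a zero-lag mixture of existing voxels to the
dataset changes no existing pairwise IC.

Per-voxel connectivity is the mean Fisher-transformed (atanh) IC between
the index voxel and all other voxels, standardised to zero mean and unit SD
across voxels ("Z-transformed connectivity"). The literature behind the
method uses null-distribution z-scores; the exact normalisation is not
stated, so across-voxel standardisation is used and documented as this
package's choice.

The contralesional test for index voxel *i* compares, with a two-tailed
Welch t-test, sample A = {atanh IC(i, j) : j in the non-tumour reference
set} against sample B = {mean over contralateral voxels c of
atanh IC(c, j)} for the same reference voxels, excluding self-pairs on both
sides. The source sentence admits a one-sample reading; the two-sample
Welch form is used for robustness to the very different variances of A and
B. Mirror pairing reflects the grid x-index across the midline.

Connectivity values are split into tertiles by rank: the top `floor(n/3)`
voxels are HFC (high functional connectivity), the bottom `floor(n/3)` LFC,
ties broken deterministically by voxel id. Whether tertiles should be taken
over all analysed voxels or tumour voxels only is unstated; the default is
all analysed voxels, configurable. A tumour is HFC-positive when at least
one HFC voxel lies inside the contrast-enhancing mask — the criterion the
survival analyses condition on.

## Aperiodic-corrected gamma power

Spectra from 1–50 Hz are estimated with Thomson's multitaper method using
29 Slepian tapers at time–bandwidth NW = (K+1)/2 = 15, eigenvalue-weighted.
The discrete prolate spheroidal sequences are computed from the classical
symmetric tridiagonal eigenproblem with Sturm-count bisection and inverse
iteration (compiled code), and their band concentrations by integrating the
zero-padded taper spectra over [−W, W]; this stays O(N) per taper and
handles minute-long recordings.

The aperiodic (1/f-like) component is fitted in semi-log space as the
Lorentzian `log10 P(f) = b − log10(k + f^χ)` with `k, χ ≥ 0` — the standard
knee parameterisation of the spectral-parameterisation literature. Because
oscillatory peaks only ever add power, the fit proceeds in two robust
stages: (1) a baseline fit on a log-spaced internal resampling of the
spectrum (equal weight per octave, so a broad high-frequency peak cannot
dominate by point count) with an L1-type iteratively reweighted loss;
(2) masking of points more than 2.5 robust SDs (MAD) above the baseline and
an unweighted refit on the remaining points, iterated twice. Recovery
benchmarks: noiseless parameter sets are recovered to better than 1%, and
across a seeded grid of (b, k, χ) with 0.02 log10-unit noise the median
exponent error is below 0.05.

Gamma power is the mean log10 residual of the spectrum above the fitted
aperiodic curve over 30–50 Hz. Averaging in log-residual rather than linear
space is a choice (the source does not say); it makes gamma power exactly
invariant to rescaling the raw spectrum, which is absorbed into the offset.
Per-subject gamma is regressed on intratumoural HFC node counts by ordinary
least squares with a two-sided slope test.

## MEA activity and synchrony

Spikes are detected on 200–3,000 Hz band-passed traces at 5 × the noise SD,
with the noise SD estimated as `median(|v|)/0.6745` — the median-based
estimator is robust to the spikes themselves, which a plain SD is not. One
event per 1 ms dead time, timestamped at the threshold crossing. Bursts are
maximal runs of ≥5 spikes with every inter-spike interval ≤100 ms. Network
bursts merge overlapping single-electrode bursts into candidate windows and
require ≥35% of active electrodes and ≥50 total spikes; the vendor's
"Adaptive" envelope algorithm is proprietary, so the interval-union rule
plus the two stated thresholds is used and documented as a substitution.
Electrodes are active at ≥5 spikes/min; MFR is spikes/duration (1,800 s
default); the weighted mean firing rate is implemented as the mean MFR over
active electrodes (the vendor convention — the literal "rate × active
count" parenthetical is dimensionally a rate times a count and is available
behind `wmfr_literal = TRUE`).

Synchrony is the area under the normalized cross-correlogram (AUNCC):
trains are binned at 5 ms, each pairwise correlogram is normalised by the
geometric mean of the zero-lag autocorrelations (so every value lies in
[0, 1] by Cauchy–Schwarz), and the area is averaged over pairs. The lag
window defaults to ±10 ms. This window is a deliberate design decision: the
correlogram *area* is invariant to any jitter that merely redistributes
coincidences inside the window, so a window much wider than the
desynchronisation being measured (e.g. ±100 ms against 5–20 ms jitter)
cannot order synchrony levels at all. A ±10 ms window puts the 5 ms and
20 ms jitter scales on opposite sides of the window edge and makes AUNCC
strictly decreasing from identical copies through 5 ms and 20 ms jitter to
independent Poisson trains. Both bin and window are configurable.

## Clinical statistics

* **Tissue contrast:** linear mixed model with tissue as fixed effect and a
  random intercept per participant, fitted by REML; the F-test uses the
  Satterthwaite denominator degrees of freedom. Channel-level and
  participant-averaged pooling orders are both exposed because the source
  description admits either.
* **FDR:** Benjamini–Hochberg step-up via `p.adjust`; the test suite holds
  it against a brute-force implementation of the definition on 1,000 random
  vectors.
* **Extent of resection:** `(pre − post)/pre × 100%`, with `post > pre` an
  error.
* **Survival:** Kaplan–Meier product-limit curves per group with the median
  as the earliest time survival reaches 0.5 ("not reached" if never), the
  two-tailed log-rank test, and median follow-up by reverse Kaplan–Meier on
  request. Recursive-partitioning survival trees and Cox models are out of
  scope by design — the cohort tables are exported in a shape those
  packages consume directly.

## The synthetic-data generators

Every generator is a pure function of its specification (which includes the
seed), and the random streams are split per participant / well / voxel so
that enlarging one count does not perturb the other units. Ground truth
(labels, coupling strengths, burst schedules, aperiodic parameters) is
returned alongside the data.

* **ECoG:** high-gamma bursts are amplitude-modulated 70–110 Hz narrowband
  noise under a raised-cosine envelope spanning 0–400 ms after onset —
  matching the band the HGp stage measures without assuming sinusoidal
  phase locking. The burst peak amplitude is 1 × the noise SD; tumour
  channels multiply it by `tumour_amplitude_ratio` and the word-frequency
  condition shifts it by ±`condition_effect_size`/2 noise SDs. Channels
  additionally share an 8–12 Hz background at 3 × the noise SD: real
  cortical recordings are dominated by low-frequency power, and without
  that background the bursty channels themselves have kurtosis well above 5
  and the pipeline's own artifact screen would reject them. The background
  is removed by the common-average reference and lies far below the
  analysis band. Latencies are Uniform(0.5, 1.8) s with a 10% slow tail
  above 2 s, and 92% of trials are correct, so the trial filters are
  genuinely exercised.
* **Voxel grid:** two mirror-symmetric hemispheres share one narrowband
  alpha oscillator; voxel *i* receives it with amplitude `base_coupling`
  (times `lesion_coupling_boost` inside the lesion) and a fixed phase lag
  on the circular lattice `{0, phase_lag, 2·phase_lag, …} mod 2π`
  (default π/4, an 8-point lattice), plus independent Gaussian noise.
  The lattice is shift-invariant on the circle, so the expected mean-IC
  profile is identical for every voxel under the null — this exact
  exchangeability is what makes the contralesional test calibrate to its
  nominal 5% level on symmetric data. Individual pairs at lag 0 or π have
  near-zero IC, but every voxel's mean IC to the rest of the grid is
  strictly positive and increases with its coupling amplitude, which is
  the quantity the HFC/LFC classification ranks.
* **Spike rasters:** homogeneous Poisson background per electrode plus
  scheduled network bursts at stated times, electrode fractions and spike
  counts (20 ms within-burst spacing, jittered); optional raw voltage with
  a 1 ms biphasic spike template at `spike_snr` × the Gaussian noise SD, so
  the 5-SD threshold is analytically checkable.
* **Spectra:** the Lorentzian-plus-Gaussian-peaks closed form tabulated on
  a fixed grid with optional log-space noise.
* **Cohorts:** exponential event times with stated per-group medians and
  independent exponential censoring whose rate is set so the expected
  censored fraction equals `censoring_fraction`. A note on precision: with
  20% censoring the KM median of an exponential at n = 200/group has a
  relative SD near 11%, so "within 15% of truth" is only a ~1.3 σ
  statement; the recovery property is asserted at n = 400/group where it
  holds with ≥90% frequency.

### What the simulations do not show

The generators emulate the *structure* each stage consumes, not the
physics: no volume conduction or beamformer leakage beyond zero-lag mixing,
no realistic MRI geometry or head models, white rather than 1/f ECoG noise
outside the injected background, stationary Poisson firing between bursts,
and exponential survival. Passing the benchmarks therefore demonstrates the
correctness and calibration of the algorithms under controlled conditions;
it does not certify performance on patient data, where artifact structure,
non-stationarity and confounding are richer.

## Problem sizes and numerical notes

The bundled demo configuration and the test benchmarks use deliberately
modest sizes — 4 participants × 8 channels × 16 trials for ECoG, 500 voxels
× 60 s at 200 Hz for connectivity, 2 wells × 300–600 s for MEA, 100–400
simulation replicates for the calibration checks — chosen so the entire
suite re-runs quickly while leaving every statistical margin comfortable;
all are configurable upward. Degenerate inputs follow a consistent policy:
zero-variance channels/trials/traces are flagged or rejected with named
reasons rather than propagating NaNs; IC values at exactly 1 are clipped to
1 − 10⁻⁶ before the Fisher transform with a warning; constant connectivity
vectors classify everything as intermediate; ties in the tertile split are
broken by voxel id so results are reproducible to the byte.
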