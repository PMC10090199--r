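---
title: "Patient-specific seizure prediction: models, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Patient-specific seizure prediction: models, assumptions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

A seizure-prediction system watches long-term scalp EEG and raises an alarm
when it believes a seizure is coming. Two timing parameters give an alarm its
clinical meaning. The *seizure prediction horizon* (SPH, 10 minutes here) is
the warning interval: after an alarm, nothing is expected to happen for SPH
minutes, giving the patient time to take countermeasures. The *seizure
occurrence period* (SOP, 30 minutes here) opens when the SPH closes: an alarm
is a *true* alarm if and only if a seizure starts inside that window, i.e.
the onset lies in `[alarm + SPH, alarm + SPH + SOP)`. Everything in this
package — labelling, alarm generation, and evaluation — is organised around
these two constants.

`preictal` implements the full patient-specific pipeline: preprocessing,
extraction of 55 univariate linear features per channel per 10-s window,
SOP/SPH labelling, chronologically split training of shallow feature-based
and compact CNN-BiLSTM classifiers as majority-vote ensembles, gap-aware
firing-power alarm regularisation, and evaluation by seizure sensitivity,
false prediction rate per hour (FPR/h) and surrogate chance-level analysis.
Because clinical long-term EEG archives are access-restricted, the package
carries a ground-truthed synthetic EEG generator, so the whole pipeline is
exercisable and testable end to end without any data download.

## Pipeline and labelling semantics

Preprocessing applies a fourth-order 0.5–100 Hz Butterworth band-pass and a
second-order 50 Hz notch, zero-phase. We realise the zero-phase cascade in
the frequency domain by applying its squared magnitude response; this is the
amplitude response of forward–backward filtering, without the phase
distortion of a causal filter, and runs several times faster on multi-hour
records. Experimental errors — flatlines, clipped (saturated) runs, and
samples beyond an absolute amplitude bound — are detected *on the raw
signal* (zero-phase filtering destroys the exact sample equality that
identifies a flatline) and the resulting per-sample validity mask is carried
forward. The first 30 minutes after every seizure onset are discarded to
avoid postictal contamination. The signal then passes through a pluggable
denoiser — identity for the "noisy" branch; a deterministic blink-regression
and muscle-burst attenuator for the "denoised" branch — and is cut into
non-overlapping 10-s windows on a fixed grid aligned to the record start.
A window containing any invalid sample is dropped; each emitted window knows
whether it is contiguous with its predecessor, because the alarm stage must
treat temporal gaps correctly.

Windows are labelled by their start time: *preictal* (class 1) inside
`[onset - SPH - SOP, onset - SPH)`, *discarded* inside the SPH, *interictal*
(class 0) otherwise. Training uses only the 4 hours before each training
seizure (2 hours in the desk profile), which bounds the class imbalance and
the training cost. The seizure-level split is chronological: the first 60%
of seizures (round half up, minimum two) train, the rest test, and each test
seizure is evaluated on the segment running from 30 minutes after the
previous onset up to its own onset.

## Features

Each channel of each window yields 55 univariate linear features: five
moments (mean, sample variance, skewness, excess kurtosis, and mean absolute
amplitude normalised by the peak), Hjorth mobility and complexity (activity
is the variance, already counted), the decorrelation time (first zero
crossing of the autocorrelation, capped at the window length), seven
absolute band powers (delta 0.5–4, theta 4–8, alpha 8–13, beta 13–30,
gamma1 30–47, gamma2 53–75, gamma3 75–90 Hz), the first six relative band
powers (the seventh is linearly redundant given the total), all 21 pairwise
band-power ratios, the total power, spectral edge frequency and power at
50/75/90% of the cumulative 0.5–90 Hz power, the alpha peak frequency, and
the five relative detail energies of a five-level Daubechies-4 wavelet
decomposition. The accounting that fixes the total at exactly 55 is recorded
in `feature_names()`. The PSD estimator is an averaged modified periodogram
(2-s Hann segments, 50% overlap): a standard bias/variance compromise for
10-s windows. Degenerate windows (constant signal, zero total power) return
0 rather than NaN in every feature, so training never sees missing values.

## Classifiers, training, ensembles

The shallow classifier is a fully connected network over the flattened
feature vector (1045 values at 19 channels): input, 50% dropout, a 2-neuron
output layer, softmax. The deep classifier consumes raw 10-s windows
(2560 × 19 at full scale): three convolutional blocks — each a unit-stride
convolution, a stride-2 convolution acting as learnable pooling, spatial
dropout (50%), swish activation, and batch normalisation, with filter counts
starting at 128 and doubling per block, kernel size 3 throughout — followed
by a bidirectional LSTM with 64 units per direction, 50% dropout, and a
softmax head. Both are trained with Adam at learning rate 3e-4 on binary
cross-entropy, using balanced batches of 64 (32 windows per class, the
preictal minority oversampled by cycling reshuffled replications), for at
most 500 epochs with early stopping at a patience of 50 epochs against a
stratified 80/20 sample-level holdout; the best-validation-loss weights are
restored. Features (or, for the deep branch, per-channel signal statistics)
are z-scored with statistics fitted on the training samples only.

Training is repeated 31 times with different seeds and the per-window hard
labels are fused by majority vote — an odd membership cannot tie. Votes are
cast on labels rather than averaged probabilities so the ensemble output is
a drop-in replacement for a single classifier at the firing-power stage.
Every stochastic choice (initialisation, batch order, dropout, holdout) is a
deterministic function of a seed, so a full run is reproducible bit for bit.

The network engine (dense, conv, batch-norm, BiLSTM layers with analytic
backpropagation, and Adam) is implemented in the package and its gradients
are verified against numeric differentiation in the test suite. In the
*standard* regime the ensemble is trained once; in the *chronological*
regime it is retrained after each tested seizure, with that seizure's
segment appended to the training data and partitioning, holdout and
normalisation refitted each round — the mechanism that lets the model track
concept drift.

## Alarms: firing power with gap handling

Raw per-window predictions are far too jittery to alarm on. The *firing
power* at window `n` is the fraction of the τ most recent 10-s slots
classified preictal, with τ = SOP/10 s = 180:

    fp[n] = (1/τ) · Σ o[k],  over the τ slots ending at window n

Slots that fall in a temporal gap (windows dropped by preprocessing), or
before the start of the stream, contribute 0 — so the firing power decays
across a gap and reaches zero once a gap spans τ slots, rather than carrying
stale evidence across discontinuities. An alarm fires when `fp` strictly
exceeds 0.5, and for the following 40 minutes (SPH + SOP, the *refractory
period*) no further alarm may fire. Written as a sum, the moving window is
taken as the τ most recent slots divided by τ, which keeps `fp` in [0, 1]
and reads exactly as "the ratio of preictal instants in the moving window".
The implementation is validated against a brute-force slot-walking
reimplementation on a thousand random gapped sequences.

## Evaluation and the surrogate test

Seizure sensitivity is the fraction of test seizures preceded by a true
alarm (at most one alarm counts per seizure). FPR/h divides the false-alarm
count by the *effective* interictal time: the duration of emitted interictal
test windows minus the refractory time consumed by the false alarms
themselves. Whether a patient's model performs above chance is decided by
surrogate analysis: holding the real alarms fixed, each test onset is
relocated uniformly at random within its own test segment (leaving room for
SPH + SOP before it) and sensitivity is re-scored; 30 such surrogates form
the chance distribution.

The p-value is the Monte-Carlo rank of the real sensitivity in that
distribution with randomised tie-breaking:
`p = (#{S > R} + U · (1 + #{S = R})) / (n + 1)`, `U ~ Uniform(0,1)`.
Sensitivity is a coarsely discrete statistic (with two test seizures it only
takes values 0, ½, 1), and a one-sample t-type test against the surrogate
distribution is badly anti-conservative under the exchangeable null. The
randomised rank p-value is exactly uniform under exchangeability, which
makes the above-chance declaration calibrated at its nominal 5% level; the
test suite verifies the calibration empirically over 500 null repetitions.
A t-type alternative remains available (`surrogate_method = "t"`). A model
is *above chance* when its real sensitivity exceeds the surrogate mean and
p < 0.05. Approaches are compared across patients with one-tailed
Mann–Whitney U tests (delegated to `stats::wilcox.test`, exact for small
untied samples) on sensitivity and FPR/h, in the three families: noisy vs
denoised input, standard vs chronological training, and deep vs shallow
classifier.

## The synthetic generator: what it emulates, and what it does not

Each synthetic channel is the sum of a 1/f-like AR(1) background
(innovation SD 6 µV, pole 0.95), an alpha rhythm (8–13 Hz resonator, SD
7 µV), a prominent theta component (6 Hz resonator, SD 11 µV — temporal
theta is a hallmark of the temporal-lobe epilepsy population the generator
emulates), and 2 µV of broadband noise. The preictal signature is a relative
band-power shift confined to `[onset - SPH - SOP, onset - SPH)`: theta
amplitude multiplied by `1 + preictal_effect`, alpha amplitude divided by
it. At `preictal_effect = 0.5` an independent periodogram threshold on
relative theta separates planted from background windows with AUC > 0.9
(verified in the tests); at 0 the generator is exactly stationary. Artefacts
are simple parametric templates — frontally weighted biphasic blinks, 20–90
Hz muscle bursts on random channel subsets, flatlines, rail-clipped
saturation — injected at Poisson times, each type from its own seed stream,
with every event recorded in the ground truth. Concept drift is a linear
decline of the alpha amplitude (floor 0.1× at long horizons), emulating the
slow suppression of the posterior rhythm across pre-surgical monitoring,
e.g. under medication tapering; declining alpha pushes interictal data
*toward* the planted preictal signature, which is exactly the failure mode
periodic retraining is meant to absorb.

What passing tests on this generator do **not** show: real preictal dynamics
are not a clean stationary band-power step; real artefacts are not
parametric templates; real drift is neither linear nor univariate; and real
inter-patient heterogeneity (electrode placement, pathology, medication) has
no synthetic counterpart. Results on synthetic patients validate the
*machinery* — labelling, leakage-free training, alarm semantics, statistical
calibration, and the directional effects of denoising and retraining — not
clinical performance.

## Numerical choices and conventions

- Zero-phase filtering via the squared magnitude response in the frequency
  domain; boundary handling is circular with zero padding to a fast FFT
  length, and boundary transients are confined to a few seconds at the
  record edges.
- Experimental-error thresholds: flatline ≥ 1 s of exactly constant samples;
  saturation ≥ 0.25 s at ≥ 99% of the observed converter rail; absolute
  amplitude > 500 µV. The thresholds are configuration, not claims about any
  particular recorder.
- Degenerate-window conventions: skewness/kurtosis/Hjorth of a constant
  window are 0; relative powers and ratios with zero denominators are 0;
  decorrelation time without a zero crossing is the maximum searched lag.
- Labels are assigned by window start time; round-half-up for the 60%
  seizure count; stratified holdout (plain random available via
  `stratify = FALSE`).
- The firing-power buffer treats pre-stream history as zeros, the same rule
  as for gaps; alarm threshold is strict (`fp > 0.5`).
- Ties in FPR comparisons count in favour of "not worse": a model that
  alarms never has FPR 0 on both branches.
- When false alarms consume the entire effective interictal time the FPR/h
  denominator is non-positive; the low-level `fpr_per_hour()` raises an
  error (the quantity is undefined), while orchestrated reports record the
  rate as infinite so that comparative experiments remain computable.

## Desk-scale profile

The full-scale configuration (31-member ensembles, 4-h training windows,
500-epoch schedule, 19 channels) is the default of `experiment_config()`.
The package's desk profile (`desk_experiment_config()`) — used by the test
suite and the bundled analysis scripts — runs 5-member ensembles, 2-h
training windows, a 50-epoch schedule with patience 8, and a compact deep
profile (2 blocks, 8 starting filters, 8 LSTM units). Synthetic desk
patients use 1–2 channels and 3–7 seizures at the minimum 4 h 30 min
spacing; recoverability experiments use `preictal_effect` 0.7–0.8, the
denoising comparison injects 120 blinks and 60 muscle bursts per hour, and
the drift comparison pairs a moderate signature (`preictal_effect` 0.5)
with a 5%-per-hour alpha decline — strong enough to produce false alarms in
a statically trained model without saturating the refractory-limited alarm
budget, and gone after retraining. These are the package's chosen desk
study conditions; all SOP/SPH/threshold/refractory constants and the
statistical machinery are identical to the full-scale configuration.

One property of the synthetic world deserves emphasis. Because the planted
signature is stationary and artefacts occur at the same Poisson rate in
training and test data, the classifier learns to ignore artefacts almost
perfectly: under every stationary artefact load we examined, both the noisy
and the denoised branch alarm conservatively (FPR/h of 0 on both sides),
and the denoising comparison verifies "not worse" through ties rather than
a strict reduction. Artefact-driven false alarms in real recordings come
from *non-stationary* artefact statistics, which the generator deliberately
does not model; the denoiser's artefact-removal efficacy is verified
separately by its signal-reconstruction error on ground-truthed recordings.
The drift comparison, by contrast, is exercised non-trivially: drift is a
train/test distribution shift by construction, the statically trained model
produces real false alarms, and chronological retraining removes them.

## Known limitations

- The deep CNN-BiLSTM trains in pure R; at the full 2560 × 19 input scale a
  31-member ensemble is a long computation, so the deep branch is primarily
  exercised at the compact desk profile. The architecture itself is
  faithful at any scale.
- The default denoiser is a deterministic signal-processing stand-in behind
  the pluggable interface where a trained artefact-removal model would sit;
  it reduces synthetic blink and muscle contamination measurably but is not
  a learned reconstruction.
- The EDF writer/reader covers continuous 16-bit recordings with a common
  sampling rate — the interchange this package needs — not the full EDF+
  specification.
- Surrogate repetitions default to 30; the randomised tie-breaking makes
  the test calibrated but means a p-value near the threshold can depend on
  the tie-break draw, which is itself seed-deterministic.
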