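---
title: "Methods: adaptive EMG pattern recognition across repeated uses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: adaptive EMG pattern recognition across repeated uses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Surface-EMG pattern recognition drives myoelectric control of prostheses
and rehabilitation robots: multichannel EMG is segmented into sliding
windows, each window is summarised by a feature vector, and a classifier
maps the vector to one of a fixed set of motion classes. A model trained in
one session degrades in the next, because re-donning the electrodes changes
their positions and the skin impedance — the feature distribution drifts
between "days" even though the motions do not. `emgadapt` implements a
complete pipeline for studying this problem: the classic 14-feature EMG
representation, two feature selectors plus a no-selection baseline, four
linear-SVM classifier strategies of increasing adaptivity, a synthetic
multi-day EMG generator with a controllable electrode-shift model, and the
reverse five-fold evaluation protocol that ties them together.

## Signal geometry and features

Recordings are 7-channel trials sampled at 1500 Hz, band-limited to
20–450 Hz, 7 s long, of which the central 5 s are analysed. Windows are
250 ms long (N = 375 samples) and advance by 50 ms, so a trial yields 96
windows and a session of 11 motions × 5 trials yields 5,280 windows.

Per channel and window, 42 feature values are computed:

* **MAV, VAR, RMS, WL** — mean absolute value, variance, root mean square,
  waveform length. The variance is deliberately *uncentred*
  (`sum(x^2)/(N-1)`): band-passed EMG is zero-mean and this is the
  convention of the myoelectric feature literature.
* **SSC, ZC** — slope-sign changes and zero crossings, counted only when
  the defining product/jump clears a threshold (10 amplitude² units for
  SSC, 25 amplitude units for ZC). The thresholds suppress noise-induced
  events and are meaningful because the synthetic generator calibrates
  typical sample magnitudes to the 10–100 range.
* **AR5, AR6, CC** — coefficients of autoregressive models of order 5 and
  6 (two separate fits), and five cepstral coefficients derived
  recursively from the order-6 fit. AR estimation uses the Burg method
  without demeaning (the model has no intercept); Yule–Walker is available
  as an option. The implementation is a vectorised Burg recursion over all
  windows at once; the test suite cross-checks it against
  `stats::ar.burg`. The cepstral recursion is the standard AR-cepstrum
  form `c_1 = -a_1`, `c_k = -a_k - sum((1 - i/k) a_i c_{k-i})`; a
  literal-transcription variant seen in parts of the applied literature is
  available behind `feature_params(cc_literal = TRUE)` for comparison.
* **MNF, MDF** — mean and median frequency of the one-sided boxcar
  periodogram (no detrending, bin width `rate/N`). MDF is the frequency at
  which cumulative power first reaches half the total; the half-total
  power itself is exposed alongside since the median is defined through
  it.
* **WTWL, WTVAR, WTMAV** — waveform length, uncentred variance and mean
  absolute value of the six coefficient vectors (cA5, cD1–cD5) of a
  five-level db2 discrete wavelet transform with symmetric (half-sample)
  boundary padding. The DWT is implemented in the package and matches the
  standard symmetric-mode convention of common wavelet libraries
  coefficient-for-coefficient.

The full vector concatenates channels channel-major: 42 × 7 = 294
dimensions. `feature_layout()` is the single source of truth for the
ordering, and `layout_index()` / `feature_groups()` map between dimensions
and (feature, channel, component) triples.

## Feature selection

All selection happens once, on day-1 data only; the selected dimension
indices are applied unchanged on later days.

**SFS** greedily grows a set of whole feature *groups* (a feature's columns
across all channels) under the Fisher separability criterion
`J3 = trace(Sw^-1 Sm)`, where `Sw` and `Sb` are the within- and
between-class scatter matrices with uniform 1/M class weighting and
`Sm = Sw + Sb` by construction. It stops when no remaining group increases
J3 by more than 1e-9; ties break in layout order, making the procedure
deterministic. Because scatter matrices restrict exactly to coordinate
subsets, the implementation computes the full 294-dim scatter once and
evaluates candidates on submatrices. `Sw` is ridge-stabilised as
`Sw + eps I` with `eps = 1e-8 trace(Sw)/D`, applied consistently on both
sides of the criterion so the lower bound `J3 >= D` survives
regularisation.

**PSO** searches the continuous unit cube: each particle position decodes
to the mask of dimensions whose coordinate exceeds 0.5, and fitness is the
validation accuracy of a linear SVM under the day-1 split (stratified
four-fifths training / one-fifth validation, z-scored on the training part
only). Defaults follow common practice: 80 particles, 50 iterations,
constriction factor w = 0.7, learning factors c1 = c2 = 2, fresh uniform
random factors per dimension per step. Design choices the canonical
description leaves open, and how we fixed them: velocities start at zero
and are clamped to ±0.5 per step; positions clip to [0, 1]; the
train/validation split is drawn once per run so fitness values are
comparable across particles and iterations; an empty mask scores 0; the
seed is mandatory and governs both the split and the swarm.

## Classifier strategies

All four strategies share one linear-kernel SVM engine (one-vs-one
multiclass, cost C = 1 by default) and one standardisation: per-dimension
mean/sd fitted on the day-1 training vectors and *frozen* — re-fitting
scalers on later days would constitute unsupervised adaptation the
protocol does not grant.

* **N-SVM** — train on day 1, never adapt.
* **I-SVM** — consume the target day's calibration fifth in order, in
  batches of 48 (a 1,056-vector fifth gives 22 batches); each step
  retrains on current support vectors plus the next batch and keeps the
  new support set. Batch order follows acquisition order to mimic online
  arrival; a seeded shuffle is available.
* **T-SVM** — TrAdaBoost instance transfer over 26 rounds. Each round
  trains on the weight-selected combined set (source = day-1 training
  rows, calibration = the fifth), computes the weighted calibration error
  `eps_t` (clipped to [1e-10, 0.499]), multiplies misclassified source
  weights by `beta = 1/(1 + sqrt(2 ln n_src / n))` and misclassified
  calibration weights by `(1 - eps_t)/eps_t`, then renormalises weights to
  sum to one. A round's training set discards source samples below 0.1×
  the mean source weight and keeps calibration samples at or above the
  mean calibration weight. From rounds 14–26 the round whose training set
  held the most calibration samples is returned (ties to the latest;
  selection by total calibration *weight* is available as an option).
* **TI-SVM** — TrAdaBoost set construction, a fresh SVM on the selected
  round's training set, then I-SVM-style incremental adaptation with the
  full calibration fifth.

Two open choices deserve note. First, the SVM engine exposes no per-sample
costs, so round models default to training on the hard weight-thresholded
subset; `adaptation_config(round_weighting = "replicate")` instead
replicates samples in proportion to weight (capped), approximating a
weighted hinge loss. Second, "the model with the most data selected from
the calibration set" is read as a count; the weight-sum reading sits behind
`cal_selection = "weight"`.

A property worth knowing when interpreting desk-scale runs: when the
combined source + calibration set is linearly separable in feature space —
which is common at a few hundred samples in 294 dimensions — every round
model classifies its training data perfectly, `eps_t` hits the lower clip
and no reweighting occurs. Boosting with a strong base learner is inert on
separable data. T-SVM and TI-SVM then still differ from N-SVM (their
training sets include the calibration fifth) and TI-SVM still refines its
support set incrementally, but the instance-reweighting machinery only
engages on data where in-sample errors occur. The dedicated TrAdaBoost
tests therefore run on low-dimensional overlapping classes where
misclassification is guaranteed.

## The synthetic generator

The generator stands in for multi-day human recordings and defines the
study conditions: 12 subjects × 5 days × 11 motions × 5 trials × 7 s at
1500 Hz over 7 channels, central 5 s analysed.

Per subject, each motion has an activation amplitude per channel. The
eleven motions are three shoulder motions, two elbow motions, and the six
shoulder+elbow compounds; basic motions draw strong activations (50–85
units) on their synergy channels (deltoids for shoulder, upper-arm/forearm
flexors-extensors for elbow), moderate secondary levels (15–35) and a low
idle floor (5–12), and compound motions superpose their components at 0.85
drive with small lognormal variation. Component sharing makes classes that
share a motion component genuinely confusable — the property that real
shoulder/elbow EMG has and that fully independent random patterns lack. A
generation-time assertion keeps all pairwise pattern correlations below
0.95.

A channel's signal is band-limited Gaussian noise (Gaussian spectral bump
at a subject-specific centre frequency in 60–150 Hz, hard-limited to
20–450 Hz), amplitude-modulated by the activation level, a per-trial
lognormal jitter (sd 0.15), an onset/offset ramp (0.75 s), and a slow
within-trial wander (sd 0.4, ~2 Hz lowpass). A flat-band noise floor 20 dB
below the weakest strong activation is added. These dispersion parameters
were calibrated once so that a day-1 linear SVM reaches roughly 98%
validation accuracy (inside the intended 85–99% "separable but not
trivial" band) and were not revisited.

The electrode-shift model perturbs later days three ways, all scaled by a
magnitude `s` in [0, 1]: per-channel lognormal gain (sd 0.25 s), a
row-stochastic near-identity crosstalk matrix (off-diagonal mass 0.15 s),
and a per-channel spectral centre drift (sd 10 s Hz). Day 1 is always the
identity and `s = 0` makes all days identically distributed. At `s = 1`
the day-1 model loses at least five accuracy points cross-day (judged
against a held-out-trial within-day reference, which unlike a window-level
split shares no trials with training); at `s = 0` the gap closes to under
two points.

Every trial's randomness derives deterministically from the master seed
via per-trial seed mixing, so any subset of the data regenerates
bit-identically.

What the generator does **not** emulate: motor-unit physiology, force or
contraction-level variation, limb-position effects, within-day electrode
migration, or inter-channel correlation beyond linear crosstalk. Passing
benchmarks on this generator shows that the pipeline's machinery behaves
as designed under controlled distribution shift — not that the same
accuracies would be obtained on human recordings.

## Evaluation protocol

Selection and base training use day 1. On each target day a *reverse*
five-fold plan is drawn, stratified by motion: each fold's held-in fifth
is the calibration set used to adapt, and the held-out four fifths are the
test set — the inversion of conventional cross-validation, reflecting that
labelled recalibration data is the scarce resource. Across folds the
calibration fifths partition the day exactly. Training time covers base
fit plus adaptation (base only for N-SVM, which never adapts); response
time is the wall-clock time to classify the test set. The summary reports
per-scheme means ± sd and paired per-subject comparisons (sign test and a
paired Wilcoxon-style p-value) for the classifier orderings; timings are
reported and only their ordinal direction is ever asserted.

## Problem sizes used in tests and scripts

The test-suite and acceptance-script benchmark runs use 3 subjects, target
days 2–3, non-overlapping 250-ms windows thinned to 8 evenly spaced
windows per trial, and all 5 folds; the no-shift control uses one target
day. These sizes are the package's chosen desk-scale configuration: they
preserve every element of the protocol (day-1-only selection, reverse
folds, batch size 48, 26 TrAdaBoost rounds) at a problem size where a full
run completes in minutes. `run_benchmark()` scales to the full
12-subject × 5-day × 96-window configuration unchanged via its arguments.

## Numerical details and degenerate inputs

* Windows must be whole numbers of samples; segmentation errors otherwise,
  as it does when a trial is shorter than the span to keep.
* Constant (zero-variance) signals yield zero AR coefficients with a
  warning; all-zero windows make spectral moments undefined and error.
* The five-level db2 transform requires at least 96 samples; shorter
  windows error with the minimum stated.
* `Sw` singular beyond the ridge rescue raises an error suggesting
  dimension reduction.
* SFS ties break by layout order; TrAdaBoost round-selection ties go to
  the latest round; both choices exist for determinism.
* Standardisation guards zero-variance dimensions by unit scale.

## Known limitations

* The CSV interchange stores raw trials at full printed precision; for
  large simulations prefer regenerating from seeds over storing signals.
* TrAdaBoost's reweighting is inert on linearly separable desk-scale
  problems (see above); conclusions about instance transfer should be
  drawn at sample sizes where in-sample errors occur.
* Timing comparisons are wall-clock and environment-dependent; only their
  ordering is meaningful.
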