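---
title: "Methods: EEG energy, ankle kinematics, and motor-imagery decoding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: EEG energy, ankle kinematics, and motor-imagery decoding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`eegkin` implements a two-study analysis pipeline for sessions in which a
seated subject wears an ankle exoskeleton that drives cyclic dorsiflexion /
plantarflexion while 28-channel EEG, 4-channel EOG and joint-angle IMU
streams are recorded. Study 1 asks how strongly band-limited EEG
instantaneous energy tracks the ankle angle, at which time lag, and how the
answer depends on the subject's cognitive state (relax vs. kinesthetic motor
imagery of the foot). Study 2 decodes motor imagery vs. relax from the same
energy features with a compact convolutional network under leave-one-trial-out
validation. Because the package must be fully testable without recordings, a
synthetic session generator with known ground truth stands in for the
experiment; this vignette documents the science, every tunable that matters,
and the design decisions that were genuinely open.

## The trial protocol

Every trial lasts 78 s at 250 Hz (EEG/EOG) and 100 Hz (IMU), partitioned as

| segment  | duration | purpose                                            |
|----------|----------|----------------------------------------------------|
| converge | 15 s     | ocular-filter convergence, no task                 |
| relax1   | 15 s     | mental relaxation                                  |
| mi       | 28 s     | sustained kinesthetic motor imagery of the foot    |
| relax2   | 15 s     | mental relaxation                                  |
| return   | 5 s      | exoskeleton returns to the home position           |

Sessions alternate *motion* trials (the exoskeleton cycles through
dorsiflexion/plantarflexion with a 4 s period) and *static* trials (the
exoskeleton is immobile); the canonical session is 11 of each. Annotation
boundaries land exactly on sample boundaries; all times are seconds from
trial start and sample indices are 0-based in the documentation.

## Preprocessing (causal throughout)

The pipeline targets eventual real-time use, so every filter is a causal,
single-pass recursion; zero-phase (forward-backward) filtering is
deliberately not used.

1. **H-infinity ocular suppression** (`hinf_clean`). Each EEG channel is an
   independent subsystem regressed on the reference vector
   \[vEOG, hEOG, 1\], where vEOG = VU − VD and hEOG = HR − HL are the
   bipolar ocular derivations and the constant absorbs drift and bias. The
   weights follow a worst-case (H-infinity) recursion with disturbance
   attenuation bound `gamma = 1.15`, weight random-walk intensity
   `q = 1e-10` and initial weight covariance `0.5·I`. These three values are
   conventional for this filter family in EEG artifact removal; they are not
   data-derived and are exposed in the configuration. The gain recursion
   depends only on the reference, so it is computed once and shared across
   channels. The protocol's 15 s converge segment exists precisely to let
   these weights settle.
2. **High-pass** (`prefilter`): 2nd-order Butterworth, cutoff 1 Hz,
   realized as a causal IIR recursion per channel; it removes the
   low-frequency residue the ocular regression leaves behind. An optional
   2nd-order IIR notch at 50 Hz emulates the hardware mains filter; it is
   off by default because the generator does not simulate mains
   interference.
3. **Montage reduction** (`select_channels`): the fifteen motor-area
   electrodes FC3, FC1, FCZ, C3, C1, CZ, CP3, CP1, CPZ, FC2, FC4, C2, C4,
   CP2, CP4, in that order.
4. **MVT normalization** (`mvt_normalize`), used only on the decoding path.
   Per channel and per analysis window, the maximum visual threshold (MVT)
   is the mean of the window's six largest *absolute* amplitudes (magnitude
   is the conventional reading of "highest amplitude"; the ranking basis is
   configurable). Window MVTs accumulate in a history whose mean is the
   running MVT; the window is divided by the across-channel mean of the
   running MVTs, making the output invariant to a global channel scaling.
   The first window processed bootstraps the state from itself - a
   subject-independent stand-in for carrying thresholds over from a previous
   session; normalization therefore differs slightly from its asymptote for
   the first few windows, which is why the converge segment is never epoched.
5. **IMU resampling** (`resample_imu`): linear interpolation from 100 Hz
   onto the 250 Hz EEG grid with clamped endpoints. Linear interpolation
   creates no content above the source Nyquist (50 Hz), which is harmless
   here because all analysis bands sit at or below 75 Hz and the band
   actually used for kinematic coupling is 8-20 Hz.

## Instantaneous energy density

All four estimators map a signal plus a band (f_lo, f_hi) to a non-negative
energy series IE(t) on the signal's own sample grid.

* **STFT** (`stft_energy`): 1 s Hann frames shifted by 0.1 s (90% overlap),
  FFT length the next power of two, one-sided PSD integrated over the band's
  bins, frame values interpolated from frame centres back to the sample
  grid. The 1 s / 0.1 s default resolves the 2 Hz gaps between the analysis
  bands while following the rhythm envelopes; both are configurable. The
  scaling is such that band energies over a tiling of (0, Nyquist] sum to
  the signal's mean power (Parseval; the test suite checks 2% on white
  noise). Edge frames use zero-padded windows.
* **Stockwell** (`stockwell_energy`): the S-transform with its
  frequency-scaled Gaussian window, evaluated on the natural FFT voice grid
  restricted to the requested band (voice spacing snapped to the configured
  `df`, default 0.5 Hz, range capped at 80 Hz for cost), via the standard
  spectrum-shifting FFT implementation; IE integrates |S|^2 across voices at
  the full sample rate. The test suite holds this implementation to 1e-8
  against a direct O(N^2) evaluation of the defining integral with a
  periodized sampled Gaussian.
* **VMD + Hilbert** (`hht_band_energy`): variational mode decomposition
  into K = 5 intrinsic mode functions, analytic demodulation of each mode,
  and IE(t) = sum of |z_k(t)|^2 over the modes whose mean instantaneous
  frequency falls inside the band. An empty assignment yields a zero series
  flagged `empty_band` rather than an error.
* **Chirplet** (`chirplet_energy`): Gaussian-windowed frames (sd 0.15 s,
  1 s support) with the quadratic phase factor exp(-i·pi·alpha·u^2);
  with `chirp_rate = 0` the operator reduces exactly to a Gaussian-tapered
  STFT, which the tests pin to 1e-10 - the consistency anchor between the
  two frame-based estimators. The chirp rate defaults to 0; a matched rate
  concentrates linear chirps, which the tests demonstrate on a 10 Hz/s
  sweep. Both squared magnitudes (|S|^2, |C|^2) are integrated, consistent
  with the energy convention used throughout.

### VMD numerical choices

The ADMM iteration (compiled, `src/vmd_core.cpp`) runs on the positive
half-spectrum of the mirror-extended signal: mode update
u_k = (x - sum of other modes + lambda/2) / (1 + 2·alpha·(w - w_k)^2),
carrier update by the spectral centroid of |u_k|^2, optional multiplier
update with rate `tau_update` (default 0 - no exact-reconstruction
constraint, the robust choice for noisy signals), stopping when the summed
relative mode change drops below `tol = 1e-7` or after `max_iter = 500`
iterations; non-convergence warns rather than failing silently. Defaults
`K = 5`, `alpha_penalty = 2000` are standard VMD practice, with K fixed by
the five-band analysis. Mode initialization offers four schemes: `uniform`
(default), `log_uniform` (geometric spacing, suited to 1/f spectra),
`bands` (the five classical EEG rhythm-band centres; used by the band
derivation, which then lets the data move the carriers), and `random`. The
reconstruction residual is reported over the central 90% of samples: the
mirror-extension joints sit exactly at the crop edges, so the outer 5% per
side measures boundary handling rather than decomposition quality - the
same edge fraction excluded when averaging instantaneous frequencies.

## Band derivation

`derive_bandset` decomposes the CZ electrode (the channel over the foot
motor representation) per trial and mental-task segment, computes each
mode's mean instantaneous frequency (unweighted time average, 5% edges
excluded), assigns each mode to the nearest canonical band *per analysis
window* before averaging - so a mode that splits contributes the mean of
its halves and a wandering mode cannot contaminate a neighbouring rhythm's
average - then averages within and across subjects. It runs on
ocular-cleaned but *not* high-pass-filtered data so the sub-1 Hz delta
component survives. The canonical set it anchors to is delta 0-2, theta
4-8, alpha/low-mid-beta 8-20, high-beta 25-40 and gamma 55-75 Hz; on
default synthetic sessions the derived means map 1-to-1 onto these bands.

## Study 1: lagged cross-correlation

Motion trials only. Per electrode and band, energies are averaged across
trials (time-locked; the movement is machine-driven and identical every
trial), and the IMU trace is the trial-averaged mean of the two insole
pitch angles (the insoles measure foot inclination directly; the wheel
IMUs are redundant 3x-geared copies). Per mental-task segment the energy
is smoothed with a multi-level centred moving average whose windows are
{0.1, 0.25, 0.5, 1.0} of one movement period; levels whose window exceeds
a quarter of the segment are skipped as degenerate (too few effective
samples to estimate a correlation). For each level the Pearson-normalized
cross-correlation is evaluated at every lag (FFT cross-products plus prefix
sums, exact), the level with the largest peak |XCF| is kept, and the
per-electrode results aggregate as the mean of |r| over the montage. Sign
convention: a negative best lag means the energy series *leads* the angle;
summaries report the lead in seconds as a positive number. The lag search
spans ±5 s but never lets the overlap drop below three quarters of the
segment, and a transition guard drops 2.5 s after and 1.5 s before every
segment boundary: task transitions carry large ERD/ERS energy transients
(smeared further by the 1 s analysis window and the smoothing) that
otherwise dominate segment-edge correlations at arbitrary lags - the same
reason the decoding study removes transition epochs.

## Study 2: motor-imagery decoding

Features are MVT-normalized 8-20 Hz energy epochs: 2 s windows shifted by
0.5 s (one prediction every 0.5 s), cut strictly inside relax1/mi/relax2 so
transition-straddling windows never exist; the protocol yields 53 MI and
2 x 27 relax epochs per trial. For the frame-free transforms (ST, HHT, CT)
0.5 s is trimmed from each border and only the central second is kept -
their border effects on 2 s windows are otherwise destructive; STFT epochs
stay whole. MVT state is per-trial (bootstrapped from the trial's first
window), so a held-out trial's data never touches another fold's
normalizer; this prioritizes fold purity over carrying thresholds across
trials, and the alternative is a one-line configuration change.

The classifier is a compact convolutional network of the EEGNet family,
implemented directly in R with hand-derived backpropagation (verified
against numerical gradients in the test suite): input average-pooling to
~25 time points (energy envelopes are slow, and the pooling factor scales
with input length so one architecture serves the 500- and 250-sample
epochs), F1 = 8 spatial filter + shared temporal filter pairs (temporal
kernel about half the pooled length; the composition is exactly EEGNet's
temporal-then-depthwise-spatial pair when the temporal filter is shared
across channels), ELU, pool 5, a separable stage (depthwise length-3
temporal convolution + pointwise mixing to F2 = 8), global average
pooling, dropout 0.35, softmax readout. Training: Adam with a cosine-
annealed learning rate (5e-3 to 1e-4), class-weighted cross-entropy
(MI epochs outnumber relax epochs 53:54 per trial only in aggregate;
weighting keeps folds robust to imbalance after epoch filtering), 60
epochs by default (a desk-scale horizon; the schedule spans whatever
`max_train_epochs` is set to), and checkpoint selection by F1 on a 20%
stratified validation split. Everything stochastic flows from the
configuration seed, so identical (data, config, seed) gives an identical
decision function.

Evaluation is leave-one-trial-out per condition: train on the other
trials' epochs, predict every epoch of the held-out trial, score per-class
accuracies. The prediction wall time per epoch is recorded so the
real-time contract (classify within the 0.5 s shift) can be asserted; it
is typically under a millisecond.

## The synthetic generator

No generative model of the recordings exists to copy, so the generator
emulates only the statistical structure the analyses rely on, with every
choice configurable:

* **Background**: 1/f pink noise, 5 uV per channel.
* **Rhythms**: five band-limited components (random-phase filtered noise
  carriers) at 0.6, 6, 15, 32 and 64 Hz with bandwidths 0.4-8 Hz and
  amplitudes 8, 5, 8, 4, 2.5 uV - prominent but plausible rhythm-to-floor
  ratios for motor-cortex EEG.
* **Movement-locked modulation**: the 15 Hz sensorimotor component carries
  a multiplicative (log-normal) amplitude modulation - the usual model for
  EEG band-power fluctuation - composed of a *session-level* smooth random
  process m(t) (depth 0.4) shared by all motion trials and an idiosyncratic
  per-trial process (depth 0.6), both band-limited to 1.2 Hz. The shared
  part is the piece that survives trial averaging, which is what makes the
  Study-1 aggregation meaningful: the movement is exoskeleton-driven and
  identical every trial, so a movement-locked rhythm modulation repeats.
* **Coupling**: the insole angle is the deterministic dorsi/plantarflexion
  cycle (4 s period, 5 degrees amplitude) plus a lag-shifted standardized
  copy of the squared modulation envelope (12 degrees sd at unit gain),
  plus 0.3 degrees of sensor noise. The envelope leak is set to dominate
  the cycle because the injected lag must be identifiable: with a
  cycle-dominated trace the cross-correlation inherits period-ambiguous
  peaks (a 2 s "lag" against a 4 s cycle is indistinguishable from
  anti-phase), which is also why an aperiodic envelope drives the coupling
  rather than the cycle itself. The default lag is 2 s with the EEG energy
  leading.
* **ERD**: during the MI segment the 8-30 Hz components lose `erd_depth`
  (default 0.3) of their amplitude through a 0.5 s raised-cosine gate, and
  the *shared* modulation depth shrinks by the same gain - event-related
  desynchronization is modelled as the loss of the coherent movement-locked
  modulation, not merely a gain change (a pure rescaling would be invisible
  to Pearson correlation). The exoskeleton-driven envelope feeding the IMU
  is not attenuated: the machine moves identically regardless of cognitive
  state. This reproduces the expected pattern: correlation drops during MI
  and recovers during relax, the drop grows with `erd_depth`, and vanishes
  at `erd_depth = 0`.
* **Ocular artifacts**: Poisson blink trains (positive ~150 uV raised-cosine
  pulses on the vertical source) and smoothed saccade steps (horizontal
  source), mixed into the EEG with a frontally-weighted gain profile and
  into the four EOG channels with known signs - so the H-infinity removal is
  verifiable against ground truth.
* **Static trials** carry the same total modulation variance, but none of
  it movement-locked, a flat IMU trace plus sensor noise, and the same ERD
  behaviour.
* **Determinism**: one master seed drives everything; per-trial seeds are
  drawn once from the master-seeded RNG, and identical (config, seed) is
  bit-identical.

What the generator does *not* emulate - and hence what green tests do not
establish about real recordings: volume-conduction geometry and realistic
inter-channel covariance (channels share modulation but not correlated
noise), non-stationarities such as fatigue or electrode drift across a
session, mains interference, movement artifacts in the EEG, genuinely
periodic movement-locked energy (see above - deliberately replaced by an
aperiodic envelope so the lag is well-defined), and between-subject
variability. Results on the study's own recordings (deposited on Zenodo,
DOI 10.5281/zenodo.14672334) additionally depend on all of these; the
package reads such data through `read_session` once arranged in the
documented layout, and the full two-study replication is the same function
calls with the session list swapped - a documented workflow, not part of
the test suite.

## Statistics module

`ks_normality` is the Lilliefors-corrected one-sample KS test (parameters
estimated from the sample, as is the case when screening empirical accuracy
tables); `friedman_test`, `wilcoxon_pairwise` (zero differences dropped,
Holm correction optional and off by default to match uncorrected pairwise
reporting), and `kruskal_wallis` delegate to the stock R implementations
behind input contracts, mean ranks and degenerate-input flags (all-tied
inputs are reported as flags or zero statistics, not errors);
`sphericity_epsilon` computes Mauchly's W from orthonormal-contrast
covariance with the chi-square approximation and the Huynh-Feldt epsilon
via its closed form, clipped at 1. Repeated-measures MANOVA beyond these
diagnostics is out of scope. An IQR-based outlier screen is deliberately
not applied anywhere by default.

## Problem sizes used by the checks

The test suite and `scripts/acceptance.R` size their simulations as
follows, chosen so every property is measured on the smallest session that
estimates it stably: lag recovery and ERD contrast on 11-motion-trial
sessions (the canonical session's motion count); band derivation on a
2 + 2 trial session; LOOCV decoding on 6-trial sessions at `erd_depth`
0.75 (separable regime) and 0 (chance regime), with the 60-epoch training
horizon; oracle equivalences on 256-sample signals (Stockwell) and 4-5 s
signals (chirplet, VMD); Parseval on 40 s of white noise. Chance-level
decoding is tested with a trial-clustered interval (mean of per-trial
balanced accuracies against 0.5) because epochs within a trial are
autocorrelated and the naive per-epoch binomial interval would understate
the variance.

## Known limitations

* The cross-correlation's lag argmax on 11-15 s segments of smooth series
  has limited effective degrees of freedom; the transition guard, the
  overlap clamp and the level-degeneracy guard exist to keep it honest, but
  per-electrode, per-segment best lags remain noisy - conclusions should
  rest on the aggregated summaries.
* The EDF writer/reader covers exactly the subset of the format the session
  layout uses (one data record, shared rate, 16-bit physical scaling); it
  is not a general EDF library.
* The classifier is deliberately compact and CPU-bound; it is not tuned for
  state-of-the-art accuracy on real EEG, and its chance-level behaviour is
  only guaranteed in the generator's class-symmetric regime.
* `imf_mean_insf` uses the unweighted time average of instantaneous
  frequency; amplitude weighting would be less noisy for weak modes but
  would change the quantity being averaged.
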