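# eegkin

Time-frequency analysis of EEG instantaneous energy and ankle kinematics
for motor-imagery brain-machine interfaces.

## What this package is for

In exoskeleton-assisted neurorehabilitation, two questions recur for anyone
building an EEG-driven (BMI) controller for ankle dorsiflexion /
plantarflexion:

1. **Does band-limited EEG energy track the joint angle, and at what lag?**
   If sensorimotor-rhythm energy over the foot motor area correlates with
   the exoskeleton-imposed movement - and the correlation weakens when the
   subject performs kinesthetic motor imagery (event-related
   desynchronization, ERD) - the correlation becomes a marker of cognitive
   engagement during therapy.
2. **Can motor imagery vs. relax be decoded from those energy features in
   real time**, well enough to start and stop the device?

`eegkin` implements both studies as a reusable, tested pipeline, comparing
four estimators of the instantaneous energy density IE(t) in a band
(f_lo, f_hi):

* short-time Fourier transform: IE(t) = ∫_band |X(t, f)|² df,
* Stockwell transform, with its frequency-scaled Gaussian window:
  IE(t) = ∫_band |S(t, f)|² df,
* variational mode decomposition + Hilbert demodulation ("HHT"):
  IE(t) = Σ_k |z_k(t)|² over modes whose mean instantaneous frequency
  lies in the band,
* chirplet transform (Gaussian window with quadratic phase, coinciding
  with a Gaussian STFT at zero chirp rate).

Around these sit a causal preprocessing chain (H-infinity ocular-artifact
suppression on the \[vEOG, hEOG, 1\] reference, 2nd-order Butterworth
high-pass, 15-electrode motor montage, running maximum-visual-threshold
normalization), data-driven derivation of the five analysis bands (0-2,
4-8, 8-20, 25-40, 55-75 Hz) from IMF mean instantaneous frequencies,
Pearson-normalized lagged cross-correlation with multi-level smoothing
(Study 1), a compact EEGNet-family convolutional classifier with
leave-one-trial-out validation (Study 2), and the non-parametric
statistical battery (Lilliefors KS, Friedman, pairwise Wilcoxon,
Kruskal-Wallis, Mauchly/Huynh-Feldt).

A synthetic session generator reproduces the experimental protocol (78 s
trials: 15 s converge / 15 s relax / 28 s motor imagery / 15 s relax / 5 s
return; alternating motion and static trials) with known ground truth - an
injected energy-to-angle lag, configurable ERD depth, known ocular mixing -
so every stage is testable without recordings. The methods vignette
(`vignettes/eegkin-methods.Rmd`) documents the generative model and every
default.

## Worked example

```r
library(eegkin)
ses <- generate_session(n_motion = 3, n_static = 3, seed = 1)
ses
#> <tf_session S1: 6 trials (3 motion, 3 static)>

cs <- correlate_study(ses, transform = "stft", bandset = decoding_bandset())
cs$aggregates
#>         band segment mean_abs_r
#> 1 alpha_beta      mi  0.6681317
#> 2 alpha_beta  relax1  0.6648908
#> 3 alpha_beta  relax2  0.8456037
cs$lag_summary
#>         band best_lag_samples   lead_s
#> 1 alpha_beta        -490.9778 1.963911

db <- derive_bandset(ses)
round(db$imf_means, 2)
#> [1]  0.64  6.05 15.11 31.99 63.89
```

Reading the output: in the 8-20 Hz band the trial-averaged EEG energy
correlates with the trial-averaged insole angle at a mean |r| of 0.66-0.85
per segment, and the best-correlating alignment has the energy *leading*
the angle by 1.96 s - recovering the generator's injected 2 s lag (the
negative `best_lag_samples` is the same fact in the signed sample
convention). The derived IMF mean frequencies 0.64, 6.05, 15.11, 31.99,
63.89 Hz sit on the generator's components (0.6, 6, 15, 32, 64 Hz) and map
onto the five canonical bands. With more trials the estimates tighten; at
a configurable `erd_depth > 0` the MI-segment correlation drops below both
relax segments.

For decoding:

```r
cv <- loocv_evaluate(ses, transform = "stft", condition = "motion")
cv$summary   # per-class and mean LOOCV accuracies with sds
```

Sessions round-trip to disk as one EDF + one IMU CSV + one JSON sidecar
per trial (`write_session` / `read_session`); result tables have fixed
schemas (`write_results` / `read_results`). Recorded sessions arranged in
the same layout run through the identical functions.

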