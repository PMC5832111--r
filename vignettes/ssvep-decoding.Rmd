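---
title: "Subject-dependent SSVEP decoding with GMM-UBM score-space features"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Subject-dependent SSVEP decoding with GMM-UBM score-space features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssvepid)
```

## The problem

A steady-state visual evoked potential (SSVEP) brain-computer interface
presents a user with several icons flickering at distinct frequencies
(here 8.5, 10, 12 and 15 Hz); attending to one of them entrains occipital
EEG at that frequency and its harmonics, and the decoder's job is to tell
which target was attended from a short multichannel segment. Two
practical complications motivate everything in this package:

1. **Imprecise stimulus rendering.** On a tablet screen with a limited
   refresh rate, the realised flicker period deviates from nominal by up
   to a few percent, differently in different stretches of a trial, so the
   spectral response peak wanders off the nominal frequency. A decoder
   that looks only at the exact target frequencies is fragile to this.
2. **Subject specificity.** The shape of the response - amplitudes,
   relative harmonic strength, and reproducible "off-target" peaks at
   non-stimulated frequencies - differs markedly between people. That
   variation is noise for a subject-independent decoder, but signal if
   the model can capture it.

The method implemented here answers both at once: score curves over the
whole 7-17 Hz band are summarised by band-wise statistics (robust to peak
displacement), and subject-specific Gaussian mixture models adapted from
a shared background model turn the subject variation into a discriminative
feature transform.

## Pipeline

`run_pipeline()` chains the stages; each is exported individually.

1. **Filtering** (`preprocess_segment()`): a 60 Hz notch (second-order
   IIR, Q = 30) followed by a 5th-order Butterworth bandpass, both applied
   forward-backward (zero phase). Bandpass edges default to 5-45 Hz,
   covering the analysis band and its second harmonics with margin; the
   edges and notch parameters are configurable in `filter_spec()`.
   Zero-phase application is a design choice: the partition features
   below are amplitude statistics and should not be phase-distorted, at
   the price of doubling the effective attenuation (the single-pass
   magnitude is the designed -3 dB at the edges).
2. **Score curves** (`cca_score_curve()`, `psd_curve()`): the maximum
   canonical correlation between the 8-channel segment and sin/cos
   references at `f` and `2f`, and the Welch power spectral density per
   channel, both over a 7-17 Hz grid in 0.1 Hz steps (101 points; all
   four targets on grid points). Two reference harmonics are the dominant
   SSVEP convention and keep the harmonic below Nyquist after filtering.
   CCA is computed by regularised covariance whitening (eigenvalue clamp
   at 1e-9 of the largest), so a flat or constant channel degrades the
   score instead of crashing the decomposition.
3. **Channel selection**: PSDA yields 8 power curves; one channel per
   subject is selected by the "first-max minus second-max" margin of the
   subject's frame-averaged PSD curve - the channel whose largest peak
   most dominates its second-largest local peak. The margin is a
   difference, not a ratio; the interpretation is configurable territory,
   and `select_best_channel()` documents the one implemented.
4. **Partition features** (`extract_features()`): the band is tiled into
   9 equal-width partitions (width 10/9 Hz; boundaries configurable via
   `partition_scheme()`). Equal width is the minimal scheme satisfying
   the design constraints - nine nonoverlapping bands covering 7-17 Hz
   with every target strictly inside a band. Per partition the CCA curve
   contributes power (mean squared score, grid-step invariant), mean,
   population standard deviation, and Shannon entropy (natural log) of
   the scores normalised to sum to one, with an all-zero partition mapped
   to the maximal entropy `log(n)` - the uniform convention, avoiding
   NaN. The PSD curve contributes mean and standard deviation only: its
   values are already powers, and entropy of near-flat power bands is
   numerically unstable. Total: 9 x 4 + 9 x 2 = 54 dimensions.
5. **Frames**: each 10 s trial is split into four nonoverlapping 2.5 s
   frames, one fusion vector each, matching the epoch granularity at
   which rendering jitter was measured. Mixture-model statistics need
   several observations per trial; four frames is the coarsest split that
   provides them while keeping 0.4 Hz-resolution spectra per frame.
6. **GMM-UBM** (`em_fit()`, `map_adapt()`): a diagonal-covariance GMM
   (the universal background model, UBM) is fitted on all subjects'
   frames by EM, then each subject's model is derived by maximum a
   posteriori adaptation of the component means towards that subject's
   frames, with relevance factor `eta = 16` (the classic GMM-UBM
   operating point; configurable). Mean-only adaptation is deliberate:
   weights and variances are inherited, which keeps subject models
   comparable component-by-component and is the minimal adaptation
   consistent with the mean-update equation. EM details: k-means++
   seeding under a fixed seed, relative log-likelihood tolerance 1e-4,
   at most 200 iterations, variances floored at 1e-6 of the pooled
   per-dimension variance. Diagonal covariances are used throughout -
   full covariances need far more training frames than a session
   provides; for the same reason mixture counts beyond 16 are not
   supported operating points (4, 8 and 16 are).
7. **Discriminative transforms** (`llr_transform()`,
   `supervector_transform()`): a test trial's frames are re-expressed as
   either (a) the S-dimensional vector of frame-averaged log-likelihood
   ratios of each subject model against the UBM, or (b) the
   S x M-dimensional supervector holding, for every subject model and
   every mixture component, the frame-averaged weighted component
   log-density. With 10 subjects these are 10 and 40/80/160 dimensions
   for M = 4/8/16. The supervector definition is a design decision: a
   literal stack of adapted mean vectors would have S x M x 54
   dimensions, which contradicts the intended S x M sizes, so the
   per-component scalar score - which reproduces those sizes and carries
   the same component-level information relative to the test data - is
   used.
8. **Decoding** (`cross_validate()`): a one-vs-one soft-margin RBF SVM
   over the transformed vectors, stratified 10-fold cross-validation,
   with the `C`/`gamma` grid search nested inside each training fold
   (3-fold inner CV; grids `C` in 0.1-100, `gamma` in 1e-3-10,
   log-spaced). Features are standardised with training-fold statistics
   only. Class labels are the four target frequencies; subject identity
   is used only to build the GMMs.
9. **Metrics**: accuracy (percent, trace over total of the pooled
   confusion matrix) and the information transfer rate. The ITR follows
   the standard Wolpaw form: bits per selection
   `B = log2 M + P log2 P + (1-P) log2((1-P)/(M-1))` scaled by `60/t`
   selections per minute. (A `t/60` prefactor sometimes seen in print
   cannot yield bits per minute - the units invert - so `60/t` is
   implemented.)

`subject_identification()` runs the complementary evaluation: fold-wise
UBM training, MAP adaptation, and argmax-of-total-log-likelihood
assignment of held-out trials to subjects, measuring how much subject
information the fusion features carry.

## The synthetic generator

No public recordings accompany this task, so `generate_dataset()` makes
the whole stack testable. Per subject it draws a response profile
(`random_profiles()`): fundamental amplitudes of 3-6 uV per target,
second-harmonic ratios of 0.2-0.5, random response phases, a random
nonnegative spatial mixing vector over 8 channels, and three off-target
peaks at subject-specific frequencies (>= 0.7 Hz away from any target) at
25-60% of the subject's mean gain. A trial is a phase-continuous
sinusoid plus second harmonic whose instantaneous period is redrawn each
2.5 s epoch from the schedule's jitter model - `jitter_measured()`
provides the per-epoch period errors measured for tablet-rendered
flicker, up to ~3.8% of the nominal period - mixed over channels and
buried in pink (1/f) plus white noise, with optional 60 Hz line
interference. The named `snr` is fundamental amplitude over in-band
(7-17 Hz) noise RMS, enforced by `calibrate_noise()`; the default
operating point is `snr = 4` with measured jitter, a regime where single
trials are visibly noisy but decodable.

What the generator does *not* emulate: real background EEG statistics
(the 1/f + white model is a controllable stand-in, not a claim of
physiological fidelity), eye or muscle artifacts, electrode drift,
inter-session nonstationarity, and latency differences across channels.
Passing tests on synthetic data therefore demonstrate the correctness
and robustness of the algorithmic chain - not clinical performance on
recorded EEG.

## Numerical choices and degenerate inputs

- CCA covariance regularisation: eigenvalues clamped at 1e-9 of the
  largest; scores clipped into [0, 1].
- Welch PSD: Hann windows, 50% overlap, mean removal per window,
  one-sided uV^2/Hz, zero-padded so the FFT bin spacing is at most the
  grid step; grid values by linear interpolation (exact when bins align).
- EM: responsibilities via log-sum-exp; empty-component soft counts
  floored at the smallest positive double; a fit with more components
  than frames errors.
- MAP: components with zero soft count keep the UBM mean (`alpha = 0`);
  `eta = 0` sets `alpha = 1` exactly on touched components.
- Ties: `identify_subject()` and the SVM grid search take the first
  (lowest-index) maximum; fold assignment rotates a round-robin offset so
  overall fold sizes differ by at most one.

## Problem sizes

The study-scale configuration is 10 subjects x 4 frequencies x 10 trials
of 10 s at 250 Hz (400 segments, 1600 frames), the trial structure of a
realistic calibration session; the test suite exercises reduced variants
(2-3 subjects, 2-5 s segments) of the same code paths. On one CPU the
full pipeline takes on the order of a minute.

## Worked example

```{r example, eval = FALSE}
library(ssvepid)

report <- run_pipeline(run_config(seed = 1), quiet = TRUE)
report
#> <ssvep_report> mode 'supervector' (80-dim), 10-fold CV
#>   mean accuracy: 100.00%   ITR: 12.00 bit/min
glance(report)
autoplot(report$cv)
```

## Known limitations

- Supervector and LLR transforms are computed from models trained on the
  full session before the decoder's cross-validation, mirroring the
  two-stage evaluation design; the GMM stage therefore sees validation
  trials (unlabeled) during UBM fitting. `subject_identification()`
  refits per fold and is free of this.
- The EDF interchange format is not implemented; segment I/O is a
  documented CSV dialect (`write_segments()` / `read_segments()`).
- Filter-bank CCA and related post-2015 SSVEP decoders are out of scope.
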