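---
title: "Interference suppression for wearable OPM-MEG: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interference suppression for wearable OPM-MEG: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the physical model behind `opmclean`, the numerical
choices made in each processing step, how the bundled session simulator is
constructed and where its realism stops, and the design decisions that are
not forced by the mathematics. It is a methods document: every number quoted
here is a parameter or a definition, not a measured result. Measured
behaviour lives in the test suite (`tests/testthat/`) and in
`scripts/acceptance.R`, which recompute everything from scratch.

## 1. The measurement model

A wearable array of optically pumped magnetometers (OPMs) samples the
magnetic field at `n` channels. Each channel `i` has a position `r_i` and a
unit orientation `o_i`, and measures the projection `o_i . B(r_i, t)`.
Because the sensors ride on the head, the recorded field mixes:

- **brain signal**: fields of neuronal currents, modelled as current dipoles
  in a spherical volume conductor;
- **homogeneous remnant-field drift**: a spatially uniform `B0(t)` from the
  imperfectly shielded environment; every sensor sees `o_i . B0(t)`;
- **movement-through-gradient artifacts**: the static remnant field inside
  the enclosure, `B_static(r) = B_c + G r` with `G` a traceless symmetric
  gradient tensor; when the head moves with rigid-body pose `(R(t), d(t))`,
  channel `i` sees `o_i(t) . B_static(r_i(t))` minus its rest value. This is
  nonlinear in the pose but well approximated by a few smooth regressors
  over short windows;
- **narrow-band line interference**: mains harmonics and equipment lines,
  each a drifting sinusoid with a fixed random coupling across channels;
- **physiological artifacts**: ocular and cardiac fields, each modelled as
  a rank-1 process (a single time course times a fixed spatial coupling);
- **sensor noise**: white, quantified as an amplitude spectral density (ASD)
  in fT/sqrt(Hz).

Two sensor populations matter: *scalp* channels on the head, and *reference*
channels fixed in the room away from the head. References see environmental
interference but (to first order) neither brain fields nor
movement-through-gradient artifacts, which is what makes synthetic
gradiometry work.

## 2. Suppression methods

### Homogeneous field correction (HFC)

The homogeneous model says the interference seen by the scalp array lies in
the 3-dimensional column space of the orientation matrix `N` (rows `o_i`).
`hfc_projector()` builds the orthogonal projector
`P = I - N (N^T N)^{-1} N^T` and `apply_hfc()` applies it to the scalp rows.
`P` removes any spatially uniform field exactly, at the cost of a rank-3
deficit in the data; the deficit is tracked on the recording
(`rank_deficit`) and honoured downstream by the ICA component cap and the
covariance rank estimate. Brain fields are spatially structured and lose
little energy to `P`; this transparency is a measured property (see the
tests), not an assumption. At least 4 magnetometers with non-degenerate
orientations are required, otherwise `N` cannot have rank 3 and the
constructor refuses.

By default HFC projects the scalp channels only, leaving references
untouched so they remain usable as regressors afterwards; `scope =
"scalp_and_reference"` is available when references should be cleaned too.

### Motion-capture regression

`regress_motion()` regresses the six rigid-body pose parameters (three
translations, three rotations) out of every scalp channel. The motion trace
is first aligned to the recording clock via the sync pulse on a trigger
channel (`sync_and_upsample_motion()`; the pulse onset is the first crossing
of half the trigger's maximum) and low-passed at 2 Hz
(`condition_motion()`), because genuine head movement is slow and the
regression must not be given a channel through which broadband noise could
be injected.

The regression runs in overlapping 10 s windows (`windowed_regress()`):
the gradient-artifact coupling is nonlinear in the pose, but over a few
seconds a linear fit in the pose parameters absorbs most of it, and
re-fitting per window tracks the nonlinearity. Details that matter:

- Each window's design matrix contains an intercept plus the regressors
  demeaned *within the window*, and regressor columns are standardised
  before QR factorisation. Field data are O(1e-10) tesla against an O(1)
  intercept; without standardisation the rank detection in the QR pivot is
  numerically meaningless. Coefficients are un-standardised before
  reporting.
- Only the regressor contribution is subtracted; channel means survive.
  The subtracted contribution references the *global* regressor mean rather
  than each window's own mean — otherwise overlapping windows disagree by a
  constant and the cross-fade between them manufactures low-frequency
  steps.
- Overlapping windows (50%) are blended with a raised-cosine cross-fade so
  coefficients can evolve without discontinuities in the output.
- Rank-deficient columns within a window are dropped and logged in the
  report rather than silently regularised.

A motion trace that is identically zero is a recorded fact about the
session, not a degenerate design: `regress_motion()` then returns the
recording unchanged.

### Synthetic gradiometry

`synthetic_gradiometry()` regresses reference channels out of scalp
channels in long (100 s) overlapping windows. Each reference is split at
20 Hz into a low band (slow environmental drift, vibration) and a high band
(line interference), because the physical coupling between a distant
reference and the scalp array differs between those regimes; the regression
gets one coefficient per band.

The band split uses complementary zero-phase Butterworth low/high-pass
pairs: forward–backward filtering squares the magnitude response, and
Butterworth low/high pairs are power-complementary
(`|H_LP|^2 + |H_HP|^2 = 1`), so the two band regressors sum back to the
original reference sample-for-sample (up to edge transients). Nothing of
the reference is lost or double-counted by the split. The outer band limits
are deliberately *not* re-imposed here: the pipeline's temporal filters run
over reference channels too, so references arrive already band-limited
identically to the data; re-filtering only the references would misalign
passband shapes and bias the fit.

Interference invisible to the references — in particular anything generated
on the head side, including brain signal — is untouched, because a
regression can only remove what its regressors span.

### Temporal filtering

`butter_zerophase()` applies forward–backward Butterworth filtering
(zero phase, squared magnitude) with odd-reflection padding of length
`min(n - 1, ceil(3 fs / f_c))` to suppress edge transients. Band-pass
requests are executed as a high-pass followed by a low-pass: a direct
band-pass design of order 2n can place poles outside the unit circle at
narrow relative bandwidths (a known failure of high-order IIR design in
transposed direct form), while the two half-designs are individually
well-conditioned. Trigger channels pass through unfiltered; epoched data
are refused (filter before epoching — transients belong to the continuous
record, not to trials).

### Spectral interpolation

`spectral_interpolate()` removes narrow lines that survive regression. The
full record is transformed with one DFT; for each target frequency the
amplitude in a ±1 Hz window is replaced by the mean amplitude of the two
flanking 1 Hz bands while the phase is preserved, and conjugate symmetry is
maintained so the inverse transform is real. Preserving phase (rather than
randomising it) keeps the operation deterministic and leaves any genuine
broadband signal crossing the notch with sensible temporal structure.
Overlapping target/flank windows are an error, not a silent merge.

The record is padded by odd reflection to a length whose prime factors are
2, 3 and 5 before the DFT and truncated afterwards: R's FFT is
O(n log n) only for smooth lengths, and a prime-length session (entirely
possible for an arbitrary recording) would otherwise make this step
quadratically slow. Reflection (not zero-padding) avoids manufacturing a
step at the boundary whose spectral leakage would contaminate the flanks.

### Projection and ICA

`ssp_from_noise()` builds signal-space projection operators from the
dominant principal components of a noise recording. `ica_denoise()` runs a
symmetric, whitened fastICA (cube nonlinearity) and removes flagged
components. Flagging is by spectral shape (low-frequency dominance without
an alpha peak) and by correlation against user-supplied template time
courses (e.g. an ECG trace); components can also be flagged manually by
index. The number of components is capped at the number of scalp channels
minus the recording's accumulated rank deficit — asking ICA for directions
that projection has already annihilated only produces noise components.

On convergence: with ~50 components extracted from OPM data, most
directions span an approximately Gaussian subspace in which the symmetric
fastICA fixed point is rotation-indeterminate, so the iteration cannot
settle below a tight tolerance no matter how long it runs. The artifact
directions (the reason for running ICA) stabilise early. `ica_denoise()`
therefore iterates to a cap (200 iterations, tolerance 1e-4) and warns on
non-convergence instead of failing; the warning is informative, not a
defect signal.

### Metrics

`welch_asd()` estimates the amplitude spectral density with Welch's method:
Hann window (periodic form), 50% overlap, one-sided densities, reported in
fT/sqrt(Hz). By default only scalp channels enter `mean_asd()` — a metric
that averages untouched reference channels into a "cleaning" comparison
understates every method that, by design, leaves references alone.
Shielding gain between two spectra is `20 log10(ASD1/ASD2)` per frequency
bin (`gain_db()`); the tests aggregate it as band power ratios where a
comparison concerns a whole band. `max_field_change()` reports the maximum
peak-to-excursion within non-overlapping 1 s chunks, in pT — the quantity
that decides whether sensors stay in their dynamic range on a moving head.

### Epoching, evoked statistics, time–frequency

`epoch_by_trigger()` cuts fixed windows around event onsets (dropping, and
logging, events whose window crosses a record boundary).
`evoked_tstats()` computes per-channel, per-sample t statistics of the
trial mean against zero after baseline subtraction; degenerate
(zero-variance) points are flagged rather than dropped.
`tfr_hanning()` convolves each trial with Hanning-tapered complex
exponentials (1–41 Hz in 2 Hz steps, 500 ms window), averages power over
trials, and trims half a window from each edge where the estimate is
partial; `baseline_db()` converts to dB relative to a baseline interval.
The TFR is computed at every sample and carries no additional decimation:
at the sampling rates involved the cost is negligible and interpolation
artifacts are avoided.

### Beamforming

`lcmv_weights()` computes a linearly constrained minimum-variance
beamformer with unit gain on the source lead fields,
`W = (L^T C_r^{-1} L)^{-1} L^T C_r^{-1}`, with diagonal loading
`C_r = C + 0.001 tr(C)/n I`. The distinctive feature is the *dual
correlated-source constraint*: bilateral auditory responses are correlated,
which biases a single-source LCMV toward cancelling them; constraining both
sources jointly in one `L` removes that bias.

In a spherical conductor a current dipole's radial moment is externally
silent, so every per-source 3-column lead-field block has rank 2 and the
naive joint constraint matrix is singular. `dual_source_leadfield()`
therefore reduces each source block to its two dominant singular vectors by
default (`reduce_rank = TRUE`), the unit-gain constraint becomes the
identity on the reduced moments, and the retained moment basis is attached
for orientation reconstruction. The full 3-column form remains available
for non-spherical models. `virtual_channel()` collapses a source's reduced
moments to one trace by the dominant singular vector of the evoked window
(sign fixed so the window peak is positive).

## 3. The session simulator

`simulate_evoked_session()` and `simulate_tapping_session()` generate
complete synthetic sessions with exact, per-component ground truth: the
returned recording is, on the magnetometer rows, *identically* the sum of
the truth components (brain, homogeneous drift, gradient-motion artifact,
lines, physiological artifacts, sensor noise). Conservation is bitwise up
to floating-point addition and is asserted in the tests; trigger rows carry
the stimulus pulse train and are excluded from the identity.

Construction choices:

- **Arrays** are Fibonacci lattices on the upper hemisphere of a 9 cm
  scalp sphere at 1 cm standoff: 43 dual-axis sensors (86 channels) for the
  evoked session, 39 (78 channels) plus two reference sensors for the
  tapping session. The two reference sensors sit at deliberately
  *asymmetric* room positions with alternating tangential seeds: a
  mirror-symmetric pair spans only a 2-dimensional orientation space, which
  makes homogeneous drift invisible along one axis of the reference set and
  silently degrades synthetic gradiometry.
- **Brain signal**: Sarvas spherical-conductor dipole fields. The evoked
  session drives bilateral auditory-cortex dipoles with a
  difference-of-Gaussians waveform time-shifted so its peak lands exactly
  at 100 ms, scaled so the noiseless sensor-space maximum hits the
  configured target (220 fT by default). The tapping session drives a left
  sensorimotor dipole with ongoing beta-band (13–30 Hz) activity whose
  envelope drops to 0.5 during movement (desynchronisation) and rises to
  1.5 after movement ends (rebound), with smooth 150 ms ramps.
- **Homogeneous drift** is a sum of sinusoids with 1/f-type amplitudes in
  0.02–5 Hz, rescaled to a 500 pT peak — large enough that, as in real
  unshielded rooms, it dominates the raw spectrum below a few hertz.
- **Gradient-motion artifacts** come from an explicit static field
  `B_c + G r` (2 nT offset, 1 nT/m traceless symmetric gradient) swept by a
  smooth rigid-body trajectory (sum of sinusoids, 0.02–0.5 Hz, rescaled to
  the configured translation/rotation ranges, with a cosine fade-in after a
  still lead-in). Both the orientation rotation *and* the position change
  contribute, so the artifact has linear and nonlinear parts in the pose —
  exactly the structure the windowed regression is meant to handle.
  References are room-fixed and receive none of it.
- **Lines** are sinusoids with slow frequency drift and fixed random
  channel couplings. Each line is flagged `ref_visible` or not: a
  reference-invisible line (e.g. one generated on the head side) is the
  control condition for gradiometry selectivity.
- **Physiological artifacts** are rank-1: a blink time course (biphasic,
  0.2–0.5 s, Poisson-timed) and a cardiac time course (Mexican-hat QRS,
  period-jittered) each multiply a fixed coupling vector computed from a
  plausible dipole position. Rank-1 truth makes "did ICA remove it"
  answerable as a projection identity rather than a heuristic.
- **Sensor noise** is white at 15 fT/sqrt(Hz)
  (`sigma = ASD * sqrt(fs/2)`).

Realism limits, stated plainly: the conductor is a sphere, not a head; the
artifact couplings are rank-1 and stationary; line drift is slow and
sinusoidal; the gradient tensor is constant over the room; sensor noise is
white and uncorrelated; cross-talk, calibration error and sensor dropout
are not modelled. The simulator is built to make *suppression methods*
testable against exact truth, not to imitate every pathology of real data.

Full-scale session sizes (hundreds of trials, several hundred seconds) are
the preset defaults; the tests and the acceptance script run scaled-down
sessions (tens of trials) chosen as this package's own trade-off between
statistical sharpness and runtime. All sizes are ordinary config
parameters.

## 4. Pipelines

`run_pipeline()` executes a declarative stage list (from
`pipeline_preset()` or a YAML file via `read_pipeline_config()`) against a
session, snapshotting the Welch ASD and max-field-change after each
recording-modifying stage; `stage_report()` tabulates per-stage band gains.
The two presets:

- **"aef"** (mobile evoked session): motion regression → HFC → bad-channel
  rejection → spectral interpolation of line frequencies → 2 Hz high-pass →
  artifact-segment detection → 40 Hz low-pass → epoching (−0.2 to 0.5 s) →
  trial rejection → evoked t statistics → dual-source LCMV virtual
  channels.
- **"tapping"** (stationary beta-band session): spectral interpolation →
  2 Hz high-pass → 80 Hz low-pass → synthetic gradiometry → HFC → ICA
  denoising → epoching (−2 to 6 s) → Hanning TFR → dB baseline correction.

Stage order encodes real constraints: filters run before epoching;
gradiometry runs after the band-limiting filters so data and references
share a passband; HFC runs after gradiometry because it would otherwise
alter the scalp channels' view of exactly the interference the references
are supposed to explain; ICA runs last among the spatial steps so its
component cap can honour the accumulated rank deficit.

## 5. Design decisions

Decisions not dictated by the model, and why they went the way they did:

- **Trigger onset = first crossing of half the pulse maximum.** Robust to
  pulse amplitude and mild low-pass smearing, needs no calibration.
- **Euler convention**: intrinsic Z-Y-X (yaw–pitch–roll), degrees at the
  interface, the common motion-capture export convention.
- **Welch conventions**: periodic Hann, 50% overlap, one-sided density;
  ASD rather than PSD because OPM noise floors are quoted in fT/sqrt(Hz).
- **Interpolation bandwidth**: ±1 Hz around each target with 1 Hz flanks —
  wide enough for drifting mains lines, narrow enough to spare
  neighbouring physiology.
- **Windowing**: 50% overlap with raised-cosine cross-fades everywhere a
  windowed operation re-fits parameters; constant-offset consistency is
  maintained by referencing global means (see above).
- **HFC scope** defaults to scalp-only, preserving references for later
  regression.
- **Diagonal loading** is expressed as a fraction of the mean eigenvalue
  (`0.001 tr(C)/n`), so the regulariser is scale-free.
- **Covariance** defaults to the mean of per-trial covariances
  (`trial_mean`), which is robust to slow level drift across a session;
  concatenated estimation is available.
- **TFR grid**: 1–41 Hz in 2 Hz steps with a 500 ms window — beta-band
  resolution at tractable cost; half-window edge trimming removes the
  partial-support estimates instead of reporting them.
- **Simulator conservation** is defined over magnetometer rows; trigger
  rows are bookkeeping, not field.

## 6. Reproducing the numbers

`scripts/acceptance.R --seed <int> --out <path>` regenerates sessions from
the given seed, runs both pipelines and the individual methods, and writes
the headline quantities as JSON. Every random draw derives from the seed;
nothing is read from outside the repository. The test suite
(`testthat::test_dir("tests/testthat")`) checks the same properties with
fixed internal seeds plus exact structural identities (conservation,
projector algebra, filter complementarity, oracle comparisons).
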