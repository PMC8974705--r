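---
title: "Component-based motion-artifact removal for locomotor HD-EMG: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Component-based motion-artifact removal for locomotor HD-EMG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hdemgclean)
```

This vignette is the package's account of its science: what the three
processing routes do, why the defaults are what they are, what the
synthetic generator does and does not emulate, and where the design was
genuinely open.

## The signal model

A 64-electrode grid (13 rows x 5 columns, 8 mm pitch, one empty corner)
records monopolar surface EMG at 2048 Hz through a 10–500 Hz acquisition
band-pass. During walking and running the observed signal is modelled as

> observed = myoelectric signal + motion artifact + amplifier noise.

Myoelectric energy during locomotion lies mostly between ~20 and ~250 Hz.
Motion artifact — electrode–skin interface motion and cable sway — is
concentrated below 20 Hz but extends into 21–50 Hz, and its amplitude
grows with gait speed and peaks around foot strike. Amplifier noise is
broadband. The analysis operates at 1000 Hz (the force-plate rate), on the
59-channel single differential along the muscle's longitudinal axis.

## The three routes

All routes share a common tail: zero-phase 20 Hz high-pass, statistical
channel rejection, stride segmentation from the vertical ground reaction
force (GRF), per-phase spatial RMS maps normalized to the array peak, and
band-wise spectral comparison against the raw differential data.

* **hpf** applies only the common tail — the conventional approach.
* **pca** and **cca** first decompose the channel data, statistically
  flag artifact components, edit the flagged components' spectra, and
  rebuild the channels. Cleaning runs twice: on the monopolar data (after
  channel screening, with subsequent neighbour interpolation of
  screened-out channels) and again on the differential data (without
  channel removal or interpolation).

### CCA by lag-1 autocorrelation

With `X_a = X(t)` and `X_b = X(t - 1)` (centred), the canonical directions
solve the symmetric generalized eigenproblem `C_s w = rho C_0 w`, where
`C_s` is the symmetrized lagged covariance and `C_0` the averaged zero-lag
covariance. Each eigenvalue equals the component's lag-1 autocorrelation,
so slow artifact-like processes rank first; stored scores are the
empirical lag-1 autocorrelations of the extracted components (they agree
with the eigenvalues to numerical precision, and the invariant is tested
at 1e-6). A ridge of `1e-9 x mean channel variance` on `C_0` keeps the
whitening stable when channels are nearly collinear — which happens by
construction after neighbour interpolation. The lag is configurable; 1
sample is the default because the artifact/EMG autocorrelation contrast at
1000 Hz is largest there, and because longer lags start ranking structured
EMG above broadband noise, which is not the separation we want.

Mixing columns are normalized to unit L2 norm, so each component's time
series carries its channel-space magnitude (for PCA the orthonormal
eigenbasis gives this automatically). This matters for the cancellation
rule below: cross-component comparisons of spectral magnitude are only
meaningful if the components share a scale convention.

### Flagging artifact components

For each component we compute the fraction of its one-sided spectral
amplitude inside the artifact band (0, 20] Hz. A component is flagged when
its fraction exceeds the cross-component mean by more than 2 SD **and**
exceeds an absolute dominance floor of 0.2. The relative part is the
statistical comparison among components; the floor encodes what "artifact
component" means physically: genuine motion-artifact components carry the
bulk of their amplitude in-band (fractions of 0.6–0.9 on synthetic data),
while a merely atypical myoelectric component (say 0.07 against a field of
0.05) is not artifact, and editing it would inject interference into
otherwise clean data rather than remove anything. For CCA, any component
with lag-1 autocorrelation above 0.999 is flagged as well — near-unit
autocorrelation marks quasi-DC drift that a band-fraction statistic can
underrate. With fewer than three components the comparison is degenerate
and nothing is flagged.

### Spectral noise cancellation

Flagged components are edited in the frequency domain: inside the
cancellation band, each bin's magnitude is reduced to the minimum of its
own magnitude and the cross-component median magnitude at that bin, with
phase preserved; out-of-band bins are untouched (`spectral_cancel()`).
The median reference means a flagged component is not zeroed — it keeps an
unremarkable amount of low-frequency content, which preserves whatever
genuine slow signal it mixed in.

Two deliberate choices here:

* **Cancellation band (0, 50] Hz, flagging band (0, 20] Hz.** Motion
  artifacts during locomotion occupy both the 0–20 and 21–50 Hz bands;
  identifying a component by where artifact is unambiguous (0–20 Hz) and
  then cleaning it across the full artifact range is the only way a
  component method can outperform a 20 Hz high-pass in the 21–50 Hz band,
  which it demonstrably does on synthetic ground truth.
* **Edits run on an even-reflection extension.** Editing FFT bins of a
  non-periodic segment is a circular operation; applied naively it
  concentrates wrap-around transients at the segment edges, which the
  subsequent high-pass smears across 21–50 Hz (on synthetic data this made
  the component routes look *worse* than plain filtering). Inside
  `clean_components()` each flagged component is extended to `c(x,
  rev(x))` — circularly continuous — edited, and cropped back.
  `spectral_cancel()` itself keeps plain per-bin semantics.

### Channel screening and interpolation

Channel screening (`screen_channels()`) iteratively rejects channels whose
log-RMS or excess kurtosis is more than 3 SD from the mean over currently
valid channels, to a fixed point (at most 8 iterations), refusing to
reject more than half the array. These are the objective criteria used in
mobile high-density EEG cleaning; the exact statistics are a package
choice since only the criterion family is standard. Zero-dispersion
statistics reject nothing, and rejecting is permutation-equivariant.
Screened-out monopolar channels are rebuilt after component cleaning as
the sample-wise mean of their valid 4-neighbours on the grid, using
pre-interpolation values throughout so the result is order-independent.

## Gait segmentation

The GRF is low-pass filtered at 40 Hz (4th-order Butterworth, forward and
backward, i.e. zero lag) and thresholded at 20 N with a 50 ms refractory
period: upward crossings are heel strikes, downward crossings toe-offs,
and only complete heel-strike -> toe-off -> heel-strike strides are kept.
20 N and 50 ms are conventional treadmill values (the threshold is not
dictated by the data model) and are configurable. Windows use the
half-open convention `[start, end)` everywhere, so stance and swing tile
each stride exactly. EMG is downsampled to the force rate beforehand, so
event indices transfer one-to-one.

## Numerical choices

* **Zero-phase filtering** is forward–backward application of a Butterworth
  design, giving amplitude response `|H(f)|^2` and zero phase. The
  `signal::filtfilt` implementation applies no edge treatment, which
  leaves large startup transients at 20–40 Hz cutoffs; the package instead
  pads by odd reflection with a pad length derived from the slowest filter
  pole (transient decayed below 1e-9) before filtering. Tests compare
  measured sinusoid gains with the closed form `butter_gain2()`, which
  includes the bilinear-transform frequency warping of the digital design.
* **Downsampling 2048 -> 1000 Hz** uses a zero-phase 10th-order Butterworth
  at 0.9x the target Nyquist followed by cubic-spline evaluation at the
  new sample times. `signal::resample`'s default polyphase filter was
  measured to leak 23 % of a 600 Hz tone past the new Nyquist and ripple
  2.6 % in the passband, failing the anti-aliasing contract; the
  replacement measures <0.01 % alias residual and <0.1 % passband error.
  Output length is `floor(n * target_fs / fs)`.
* **Spectra** are single-taper one-sided FFT amplitudes, scaled so a unit
  sinusoid at a bin centre has amplitude 1. Band sums use the half-open
  convention `(low, high]`, with bands labelled 0–20, 21–50, 51–100,
  101–500 Hz.
* **Degenerate inputs**: rank-deficient PCA retains positive-eigenvalue
  components (logged); two-channel flagging and two-channel MAD exclusion
  are no-ops; an RM-ANOVA cell with zero error and zero effect yields
  `F = NA`, `p = 1`.

## Statistics

Per-location method comparisons use a one-way repeated-measures ANOVA with
subject as the blocking factor, computed in closed form
(`F = MS_method / MS_error` with `(k-1)`, `(n-1)(k-1)` degrees of
freedom) and cross-checked in the tests against `stats::aov` with an
`Error(subject)` stratum. P-values are Benjamini–Hochberg adjusted across
locations (`stats::p.adjust`, verified in tests against a brute-force
step-up implementation); no sphericity correction is applied by default.
Spectral averaging across channels excludes channels more than 10 scaled
MADs from the cross-channel median summary amplitude. Percent band
decreases are computed per channel and then averaged (the pooled
alternative changes emphasis toward high-amplitude channels and is not
the default).

## The synthetic generator

`simulate_hdemg()` emulates the study conditions so the pipeline can be
validated against ground truth:

* **Clean EMG**: 20 motor units, each a Gaussian-second-derivative MUAP
  (width parameter 0.8–1.8 ms, support ~5–11 ms) with amplitude decaying
  exponentially (space constant 2 electrodes) from a random territory
  centre, driven by gamma-renewal spike trains (shape 16, 15–35 Hz) gated
  to stance (gastrocnemius-like) or swing (tibialis-anterior-like). Peak
  amplitudes 60–180 uV give channel RMS in the tens of microvolts,
  typical of running surface EMG.
* **Artifact**: two random-walk processes low-passed at 20 Hz with a
  gentle 2nd-order skirt — ≥90 % of artifact energy below 20 Hz with a
  realistic tail into 21–50 Hz — modulated by a foot-strike-locked
  envelope (Gaussian bumps, 60 ms SD, on a 0.3 baseline) and coupled to
  the array through a smooth spatial trend times per-electrode lognormal
  heterogeneity. The heterogeneity is essential: a perfectly smooth
  loading would be cancelled by the differential montage, contradicting
  the premise that differential recordings remain contaminated.
* **Speed scaling**: the speed label maps to an artifact multiplier
  (1.2/1.6/2/3/4/5 m/s -> 0.4/0.6/1.0/1.6/2.4/3.2, base 12 uV RMS),
  encoding that artifact grows with locomotion speed. The default
  condition is 5 m/s — the regime where method differences matter.
* **Noise**: i.i.d. Gaussian, 1.5 uV SD, the input-referred noise class
  of modern HD-EMG amplifiers (<2 uV RMS).
* **GRF**: half-sine stance bumps (peak `700 + 220 x speed` N) at the
  stride cadence; stride period 0.7 s with stance fraction 0.35, typical
  of fast running.

What it does **not** emulate: volume-conductor anatomy, muscle-fiber
conduction velocity and MUAP propagation, fatigue, electrode impedance
drift, power-line interference, or between-subject variability. Passing
tests on this generator therefore demonstrate that the pipeline removes
spatially coherent low-frequency contamination while preserving
higher-frequency content of multichannel signals — not that any specific
physiological effect would be observed in human data.

Event recovery on generated GRF is tested with detection on the raw
synthetic trace: the construction is already band-limited, and the 40 Hz
zero-phase filter (meant for real, noisy force plates) would shift the
20 N crossing of an idealized sharp bump onset by more than the
construction tolerance.

## Validation scale and determinism

The test-suite and acceptance problems use the default 20-stride, 64 x
~28000-sample condition for end-to-end checks and 4–8 strides for unit
checks; decomposition round-trips are validated on 64 x 5000 random
matrices and the null calibration of the FDR-corrected location ANOVA on
200 simulated 8-subject x 3-method x 59-location sets. These sizes make
every property measurable with comfortable margins while keeping a full
run inexpensive. All randomness flows from a single seed (fanned to
per-component sub-streams in the generator), and the pipeline itself is
deterministic: identical input, configuration and seed replay
bit-identically, which the acceptance script verifies by hashing.

## Signal-preservation metric

The acceptance script reports the correlation between the CCA-cleaned
differential and the true clean differential, band-passed to 21–500 Hz,
pooled over valid channels *excluding differential pairs that touch an
interpolated electrode*: an interpolated channel carries its neighbours'
average by construction, so its waveform fidelity measures the
interpolation geometry, not artifact removal. Amplifier noise — present in
the observed input and untouched by all three methods by design — sets the
ceiling of this correlation.

## Known limitations

* The cancellation reference (cross-component median) assumes most
  components are artifact-free at any given bin; arrays where artifact
  spreads across many components (e.g. after severe electrode
  displacement) would blunt the cleaning.
* Flagging assumes at least three components and loses power for very few
  channels.
* The RM-ANOVA assumes complete blocks; locations with missing cells are
  skipped rather than imputed, and no sphericity correction is applied by
  default.
* EDF support is a minimal single-record reader/writer intended for
  exchange, not for streaming acquisition files.
* The second (differential) cleaning pass operates on a near-singular
  covariance when channels were interpolated; the ridge handles it, but
  components beyond the array's effective rank are uninformative there.
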