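---
title: "Filtering respiratory motion artifact from infant rs-fMRI motion traces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Filtering respiratory motion artifact from infant rs-fMRI motion traces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(respkit)
```

## The problem

Frame censoring ("scrubbing") removes fMRI volumes whose framewise
displacement (FD) exceeds a threshold, conventionally 0.2 mm, on the premise
that apparent head motion disrupts the BOLD signal. With sub-second
(multiband) repetition times, however, the respiratory rate of a sleeping
infant or toddler — roughly 0.2–0.6 Hz, i.e. 12–36 breaths per minute — is
below the Nyquist frequency (`1/(2·TR)` = 0.625 Hz at TR = 0.8 s) and
appears unaliased in the rigid-body realignment parameters, concentrated on
the phase-encode axis. This oscillation is a magnetic-field (B0) effect of
chest motion, not true head displacement: it does not disrupt the BOLD
signal, yet it pushes FD over threshold on a large fraction of frames and
can discard most of a session.

The remedy is a band-stop ("notch") filter applied to the motion-parameter
traces before FD is computed. Frames lost to the respiratory oscillation are
recovered; genuine movement spikes remain above threshold and are still
censored. respkit implements this chain end to end, together with a
synthetic cohort generator so every stage can be validated against known
ground truth.

## Framewise displacement

FD at frame $t$ is

$$\mathrm{FD}_t = \sum_{i \in \mathrm{trans}} |\Delta p_i(t)|
  \;+\; r \sum_{i \in \mathrm{rot}} |\Delta \theta_i(t)|,$$

the sum of absolute frame-to-frame differences of the three translations
(mm) and the three rotations converted to arc length at head radius $r$.
The radius is not fixed by the FD definition itself; `compute_fd()` defaults
to 35 mm, an age-appropriate infant/toddler head size, with 50 mm available
for comparability with adult pipelines. Frame 0 has no predecessor and is
assigned FD = 0, so it is always retainable on FD grounds. The boundary case
FD exactly equal to the threshold is retained: censoring removes frames that
*exceed* the threshold, and the measure-zero boundary is assigned to
retention.

Rotations are stored internally in radians and translations in mm;
`read_motion()` takes explicit `dialect` and `rotation_columns` flags
because realignment tools disagree on both, and a silent degree/radian
mix-up corrupts FD by a factor of ~57.

## Detecting the respiratory band

`motion_spectrum()` estimates the power spectrum of each motion parameter
with a Welch-averaged periodogram: Hann window, 50% overlap, segment length
`min(T, 256)` frames. Welch averaging trades frequency resolution
(~0.005 Hz at TR = 0.8 s) for variance reduction, which matters on
~420-frame runs. Columns are linearly detrended by default; an option to
work on first differences is not provided because the detrended-position
spectrum already localizes the respiratory peak to within a grid bin in
testing.

A subject's respiratory peak (`find_resp_peak()`) is the median, across the
selected parameter axes, of the frequency of maximum power within a search
band (default 0.2–0.6 Hz). The default axis set is the phase-encode
translation alone, where the artifact is strongest; all six parameters can
be used instead, and with multiple axes the median across axes is taken.
A peak is flagged *low-prominence* when no selected axis has peak power at
least 3× its median in-band power; flagged subjects are excluded from
cohort cutoff derivation (with a message), since a flat spectrum's argmax is
noise.

`alias_frequency()` folds a true frequency into `[0, 1/(2 TR)]`. At
conventional TRs of 2–2.5 s a 0.4 Hz respiratory rate folds to near DC,
which is why the artifact went unnoticed in single-band infant data.

## Data-driven notch design

`design_notch()` derives cohort cutoffs from the unflagged subject peaks:
the center is the median peak frequency, and the stopband edges are the 25th
and 75th percentiles (linear-interpolation percentiles — the span of the
second and third quartile groups). If the interquartile span is narrower
than `min_width_hz` (default 0.06 Hz) it is widened symmetrically about the
center, so a homogeneous cohort still yields a usable band. Cutoffs are
derived at the group level; per-subject cutoffs are possible in principle
but add nothing in practice, so they are not a default path.

Two presets are provided for ages 8–24 months: `notch_preset("toddler")`,
the recommended slightly widened 0.25–0.50 Hz band, and
`notch_preset("quartile_derived")`, the narrower 0.28–0.48 Hz quartile-derived
band.

Two filter families are supported because both are in common institutional
use and behave interchangeably here: a second-order IIR notch biquad
(constrained: unit gain at DC and Nyquist, a zero at the center frequency,
−3 dB bandwidth equal to `hi - lo`) and a Butterworth band-stop (default,
order 2) designed via `signal::butter()`. `apply_notch()` filters all six
parameter columns identically — the artifact leaks from the phase-encode
axis into the other planes and mixes with true motion there, so filtering
only one axis would leave artifact behind.

### Numerical choices in the filtering core

* **Zero-phase application** (forward–backward) is the default so the
  filtered trace has no lag and stays frame-aligned with censoring; the
  effective magnitude response is squared, deepening the notch.
* **Edges**: each pass uses odd-symmetric extension of `3 × (n_coef − 1)`
  samples at both ends plus steady-state initial conditions scaled to the
  first sample. On 420-frame runs edge transients are non-negligible;
  with this scheme a constant trace passes unchanged to better than 1e−9
  and a 0.05 Hz passband tone is preserved within 5%.
* **Stability** is checked from the pole radii at application time, and a
  stopband edge at or above Nyquist is rejected with a pointer to
  `alias_frequency()` (at such TRs the artifact is aliased and a notch at
  the breathing rate is meaningless).
* The filter kernel is a direct-form-II-transposed recursion in compiled
  code; coefficients are designed in R.

## Censoring and retention

`censor()` thresholds an FD trace into a frame mask; `retention()` pairs
unfiltered and filtered FD traces and reports usable minutes
(`kept × TR / 60`, unrounded) for each. No temporal augmentation (censoring
neighbors of bad frames) is applied. On respiration-dominated synthetic
runs, filtering raises retained minutes for every subject, while ground
truth movement-spike frames stay censored under every tested band — the two
qualitative properties that motivate the method.

## Connectivity and reliability

`bandpass_interp()` linearly interpolates censored frames from the nearest
retained neighbors, demeans, and applies a zero-phase second-order
Butterworth band-pass (default 0.008–0.09 Hz; 0.005–0.1 Hz is a supported
alternative convention). Interpolation prevents censored gaps from ringing
through the filter; the mask must be re-imposed downstream, and
`fc_matrix()` does so — correlations use retained frames only, with a
configurable floor (default 10 frames, excluded subjects reported).
Nuisance regression is out of scope: the package accepts externally
denoised timeseries, and the generator emits signals that play that role.

`network_blocks()` summarizes a parcel correlation matrix into
network-block means; within-network cells average off-diagonal pairs only
(self-correlations excluded), and singleton networks yield an undefined
within cell reported as `NA`. `paired_ttest()` compares two conditions
across subjects on Fisher-z transformed values, per parcel pair or per
block; z-transforming before averaging/testing is standard for correlation
inference. No multiple-comparison correction is applied by default (an FDR
flag exists).

`split_half()` enumerates usable frames in acquisition order across
concatenated runs and assigns the first ⌊U/2⌋ to half 1 and the next ⌊U/2⌋
to half 2, dropping at most one frame so the halves are always equal-sized;
with two equal fully-usable runs this puts one run in each half. An
odd/even-frame split is available for sensitivity checks.
`reliability_curve()` then correlates the two halves' upper-triangle FC
vectors per subject and reports mean, SD, and SE across subjects per FD
threshold (default grid 0.05–0.5 mm in 0.05 steps); both SD and SE are
emitted so shaded bands can be drawn either way. Subjects whose halves fall
below the frame floor are excluded at that threshold.

## The synthetic cohort generator

`gen_motion()` builds a realignment trace as drift + respiration + spikes +
noise:

* **Respiration**: a frequency-wandering sinusoid, not a physiological
  waveform — sufficient to produce the narrow-band FD power the method
  targets. Defaults: subject frequency ~ N(0.40, 0.05) Hz (24 ± 3 breaths
  per minute, a realistic sleeping-toddler range), within-run wander SD
  0.01 Hz, amplitude 0.15 mm on the phase-encode translation with 30%
  leak (random phase) into the other translations and a small rotational
  component. At TR 0.8 s this amplitude makes the respiratory FD
  oscillation peak near 0.25–0.35 mm, crossing the 0.2 mm threshold every
  breath — the regime the method exists for.
* **Spikes**: discrete repositioning events at 2 per minute — a log-normal
  displacement (median 1 mm, floor 0.5 mm) on a non-phase translation
  axis, held for 4–15 frames and then released, with an 8-frame refractory
  gap. A repositioning is the physically right realignment signature of a
  gross arousal movement: the head moves and stays, so the trace shows two
  transition edges rather than a one-frame blip. The floor keeps even the
  smallest event's transition edge above 0.2 mm after any reasonable notch
  (the zero-phase band-stop retains ~60–70% of an edge), so ground-truth
  spike frames are censored by construction in both arms.
* **Drift and noise**: random per-axis linear drift (SD 0.1 mm/min) and
  white realignment-estimation noise (SD 0.01 mm per translation,
  1/50 of that in radians per rotation).

`gen_bold()` draws network-structured Gaussian parcel signals (default 50
parcels, 5 networks, within-network correlation 0.35, between 0.05),
temporally smoothed with a hemodynamic-like Gaussian kernel (SD 2 s), and
adds spike-locked corruption: the movement *transition* frames, convolved
with a short causal decay kernel (1, 0.6, 0.3) and scaled by
`corruption_gain` (default 2 signal-SDs), enter all parcels with random
weights (mean 1, SD 0.5). Respiration does not enter BOLD at all — the
identifiability premise that makes the respiratory FD component safely
filterable. A `resp_coupling` parameter (default 0) can violate that
premise deliberately for sensitivity experiments.

`gen_cohort()` draws per-subject frequencies and 2–4 runs per subject, is
fully deterministic under its seed, and can write everything to disk in the
package's plain-text formats.

### What passing tests do and do not show

The generator emulates the *statistical* signatures the pipeline keys on:
narrow-band phase-axis power, sparse large spikes co-located with global
signal disruption, block-structured parcel covariance. It does not emulate
k-space/B0 physics, cardiac or other physiological noise, distance-dependent
artifact, nuisance-regression residuals, or non-Gaussian BOLD structure.
Tests passing on this cohort show the pipeline's operations are correct and
its qualitative claims (retention gain, spike censoring, reliability gain)
hold under the stated model — not that effect sizes transfer to real scans.

One directional claim does *not* reproduce under this model and is worth
stating plainly: comparing filtered- vs unfiltered-censored connectivity
with a paired t-test on Fisher-z values, within-network cells here come out
slightly *negative* (the unfiltered arm's sparse, interpolated,
band-passed data carries relatively more residual spike corruption and
small-sample z inflation), whereas on real data the filtered arm shows
higher-magnitude within-network FC. In a generator where respiration is
strictly BOLD-orthogonal, both arms estimate the same population
correlations and the t map direction is driven by these second-order
effects; the real-data direction presumably rides on artifact and nuisance
structure that is deliberately outside this model. The accuracy statement
that *is* supported — and tested — is that filtered-arm block estimates are
closer to the ground-truth correlations (lower RMSE) than unfiltered-arm
estimates in ~96% of cohort draws.

## Problem sizes used in the shipped checks

The test suite and the acceptance script regenerate everything they
measure: 1,000 random traces for the FD oracle, 100 thirty-subject
motion-only cohorts for cutoff recovery, 50 ten-subject BOLD cohorts for
block-recovery RMSE, and one 20-subject, 3-runs-each cohort for the
reliability curves. These sizes give stable directions and quartiles on a
single CPU in well under an hour; all are parameters of the corresponding
functions and can be scaled up.

## A worked example

```{r example, eval = FALSE}
library(respkit)

# simulate a cohort, derive data-driven cutoffs
cohort <- gen_cohort(30, bold_params = NULL, seed = 7, runs_per_subject = 1)
peaks <- lapply(cohort$subjects, function(su)
  find_resp_peak(motion_spectrum(su$runs[[1]]$trace)))
spec <- design_notch(peaks)
spec

# filter one subject and account for usable data
trace <- cohort$subjects[[1]]$runs[[1]]$trace
fd_raw <- compute_fd(trace)
fd_fil <- compute_fd(apply_notch(trace, spec), filtered = TRUE)
retention(fd_raw, fd_fil, threshold_mm = 0.2)
```

## Known limitations

* Parcel-level only: no NIfTI/CIFTI image I/O, no voxelwise grayplots, no
  image-space preprocessing; network assignments are inputs, not inferred.
* The boundary between respiration and true motion at overlapping
  frequencies is not modeled; like the method itself, the filter removes
  everything in the stopband.
* Within-subject respiratory variability of sleeping toddlers is not well
  characterized; the generator's wander SD is a configurable placeholder.
* Reliability is split-half within session; test–retest designs and ICCs
  are out of scope.
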