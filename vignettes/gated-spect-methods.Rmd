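---
title: "Time-modified OSEM for ECG-gated myocardial perfusion SPECT: models and methods"
author: "gatedSPECT authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Time-modified OSEM for ECG-gated myocardial perfusion SPECT: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Fixed forward ECG gating divides every R-R interval into bins of fixed
length, starting at the R wave; the bin length is one `nBins`-th of the mean
accepted R-R interval. The heart, however, completes one full cycle per
beat, whatever that beat's length. Beats shorter than the mean therefore end
before the last gating bin fills up, so over a whole acquisition the last
ECG bin accumulates less acquisition time — and fewer counts — than the
early bins. With plain OSEM reconstruction, which implicitly assumes equal
acquisition time everywhere, the last-bin image comes out dimmer. A dim
final frame distorts every myocardial time-activity curve at its final
sample and, through the first-Fourier-harmonic (FFH) fit, biases the phase
histogram indices used to quantify left-ventricular dyssynchrony.

The time-modified OSEM (TOSEM) reconstruction implemented here scales every
transition-matrix block by the acquisition time of its projection angle and
ECG bin, `H_l = tau_l P_l R_l`, where `P_l` is the forward projection
(including the collimator-detector response) and `R_l` the image rotation to
the detector frame. The acquisition time then also enters the sensitivity
term `sum_l H_l^T 1` of the multiplicative EM update, so per-bin images are
reconstructed on a common activity-rate (counts per second) scale: a
half-time last bin is automatically scaled back to the level of the others,
with its larger Poisson noise honestly propagated rather than hidden.

## The phantom and what it does and does not emulate

`lvPhantomSpec()` describes a short-axis annular left ventricle. Local wall
thickness follows

    t(theta, s) = t_ED * (1 + c * (1 - cos(theta - delta_s)) / 2)

at cycle phase `theta` in sector `s`, with contraction fraction `c`
(default 0.3) and per-sector delays `delta_s`; the wall thickens inward
(fixed epicardium) and voxel activity is proportional to local thickness,
emulating the partial-volume count brightening that makes wall counts track
thickening. Counts are therefore minimal at end-diastole and peak at
end-systole, and a delayed sector's count-phase curve is the reference
curve shifted by its delay — which is exactly the signal phase analysis
measures.

The generator emulates a step-and-shoot dual-detector style acquisition:
each projection angle consumes a fresh contiguous stretch of one long
simulated beat series (beats are assigned to the angle whose dwell window
contains their R trigger), acceptance uses a +/-20% window around the
single-pass mean R-R, and each accepted (beat x bin) overlap contributes
its duration times the forward projection of the phantom at the overlap's
midpoint cardiac phase. The midpoint (one-point) quadrature keeps the error
second order in the bin width. Observed counts are Poisson.

What the phantom does *not* model: anatomy beyond an annulus (no liver or
gut activity, no apex closure), attenuation and scatter (not modelled in
the reconstructions either), detector dead time, arrhythmia beyond a
truncated-Gaussian R-R distribution, and any trigger-device behaviour.
Passing tests on this phantom therefore show that the algorithms behave as
designed under controlled conditions; they do not certify performance on
patient data.

## Study conditions (defaults, chosen once)

* R-R intervals: truncated Gaussian (lower cut 0.3 x mean; mean 0.9 s by
  default — a typical resting heart rate; the distribution shape of real
  patients is unknowable from summary statistics).
* Desk-scale camera: 32 angles over 180 degrees, 48 x 48 x 16 grid of 4 mm
  voxels, circular 150 mm orbit, 10 s per angle. A clinical-scale preset
  (64 angles, 96 x 96, 6.22 mm) is available via
  `spectGeometry(clinicalScale = TRUE)`. The desk dwell of 10 s (instead of a
  clinical 30 s) keeps a full study at roughly 1.7 million counts, enough
  for stable phase analysis.
* Collimator-detector response: Gaussian with FWHM(d) = 3 mm + 0.045 d
  (about 7.5 mm at 10 cm), an LEHR-like choice; both parameters are
  configurable because published hardware descriptions rarely pin them
  down.
* Rotation: Gaussian interpolation with sigma_r = 0.42 voxel (about one
  voxel FWHM) — small enough to limit blur, large enough for smooth
  weights — with an exact snap when a back-rotated point lands on a grid
  node, so 0- and 90-degree rotations are exact.
* Reconstruction: 10 iterations x 8 subsets, subsets `l == s (mod 8)`
  processed in bit-reversed order, uniform unit start image, 1e-12
  positivity guards. Post-processing: 3-D Gaussian smoothing (sigma = 1
  voxel, mirror boundaries) then a cylindrical mask two voxels beyond the
  epicardium.
* Phase analysis: 36 x 12 mid-wall sample points with radial max-count
  search, FFH fit at bin-centre phases, 5% lowest-amplitude discard
  (undefined-phase points first), 360-bin histogram; BW is the smallest
  circular arc holding 95% of retained phases, StD the sample SD after
  re-centering about the circular mean, ENT the histogram entropy
  normalised by log2(360) in percent.
* Population: per-subject mean R-R uniform in 0.8-1.0 s, normalized R-R SD
  assigned on an evenly spaced 0.02-0.12 grid (so the range is covered at
  any population size), two adjacent delayed sectors with delay uniform in
  0-90 degrees, all derived deterministically from one master seed.

## Design choices where the design was genuinely open

*Acceptance reference.* What the +/-20% window is relative to is not
observable from outside a trigger device; the single-pass mean of all beats
is the simplest defensible reading and is used throughout. SD_R-R uses the
sample (n-1) denominator.

*Thinning calibration.* Reduced activity-ratio data sets are produced by
binomial thinning of the last bin with retention probability calibrated on
raw counts (the reconstruction total is approximately proportional to
counts; verified as a property). An optional `refine = TRUE` step
recalibrates once against a reconstructed activity ratio.

*Baseline level for the reliability study.* A subject whose native
last-bin count ratio is below the top requested level cannot be thinned
*up* to it. `runPart2(levelPolicy = "exclude")` drops such subjects,
mirroring a selection of patients with AR above the top level;
`levelPolicy = "cap"` instead caps each subject's levels at the native
ratio, so a population with a wide HRV range can still be studied end to
end — its top "level" is then the subject's native data. The shipped
reliability target uses `"cap"` with 14 subjects spanning the full HRV
range.

*BW definition.* Commercial phase-analysis software does not publish its
bandwidth rule; the minimal 95% circular arc (coverage configurable) is
declared here. Absolute BW/StD/ENT values are therefore not comparable to
any specific commercial implementation, while *changes* of these indices
between reconstructions of the same data are.

*Phase convention.* Phase 0 is the R wave; TAC sample phases sit at bin
centres, `360 (k - 1/2) / K`; the fitted phase is the position of the TAC
maximum. The first Fourier coefficient is taken with the `exp(+i theta)`
kernel so that `y = A0 + A1 cos(theta - phi)` returns `phi` itself.

*Empty bins.* A TOSEM bin with zero acquisition time everywhere is an
error, not a silent zero image: there is no data and no sensitivity, and
continuing would hide it. Zero-sensitivity voxels within an otherwise valid
bin are set to zero and frozen.

*Units.* The projector returns counts per second per detector bin for an
image in counts per second per voxel; the duration factors live in the
system matrix (TOSEM) or in the data (OSEM), never in both.

## Numerical behaviour worth knowing

* The forward/back projector pair is an exact adjoint (relative 1e-6 on
  random fields), which guarantees the monotone Poisson likelihood of the
  MLEM special case.
* Gaussian-interpolation rotation is exact at lattice-aligned angles
  (0, 90, 180, 270 degrees) thanks to the snap rule; at oblique angles it
  behaves like an extra blur of roughly sigma_r, which is visible as a few
  percent deviation when projecting a worst-case single-voxel source, and
  as under 2% round-trip error on smooth objects.
* Mirror-boundary smoothing conserves the mass of structures more than one
  kernel width from the volume faces; the LV sits well inside.
* With zero HRV the activity ratio is still below 100%: the last bin sits
  near end-diastole where the wall is thinnest, so wall motion alone
  depresses it by several percent. This matches the observation that even
  the calmest real subjects do not reach 100%.
* Reconstruction-scale blur biases full-sector phase averages towards
  neighbouring sectors; `sectorMeanPhases()` therefore drops the sample
  ring next to each sector boundary when recovering programmed delays.

## Problem sizes used by the shipped checks

The test suite and the acceptance script run entirely at desk scale: the
reliability study uses 14 subjects at two thinning levels (TOSEM only,
about 25 s per subject end to end), the population sign study uses 20
subjects with both reconstructions, and module tests use a 24 x 24 x 8
phantom with 16 angles. These sizes were chosen as the smallest populations
whose between-subject variance comfortably identifies the signs and
concordances of interest.

## Known limitations

Single first harmonic only (no multi-harmonic phase analysis); no
attenuation, scatter or resolution recovery beyond the CDR model; no
ejection-fraction or volume computation; the phantom's wall is an annulus
with analytically known surfaces, so myocardial sampling needs no surface
detection — users analysing externally supplied gated series must provide a
sampling grid that matches their geometry.
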