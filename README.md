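# gatedSPECT

Tools for studying — and correcting — the heart-rate-variability (HRV)
artifact of fixed forward ECG gating in myocardial perfusion SPECT.

## The problem

Gated perfusion SPECT divides each R-R interval into fixed-length bins
(typically 8) starting at the R wave, with bin length Δ = mean accepted
R-R / 8. Because short beats end before the last bin fills, the last ECG
bin accumulates less acquisition time than the others; reconstructed with
ordinary OSEM it appears artificially dim. That dimming perturbs every
myocardial time-activity curve at its last sample and biases the phase
analysis indices used to quantify left-ventricular mechanical dyssynchrony:
histogram bandwidth (BW), phase standard deviation (StD) and entropy (ENT).

The package implements the time-modified OSEM (**TOSEM**) reconstruction,
in which every transition-matrix block carries the acquisition time of its
projection angle and ECG bin,

    OSEM:   H_l = P_l R_l
    TOSEM:  H_l = τ_l P_l R_l

with `P_l` a rotation-based parallel-beam forward projector including a
distance-dependent Gaussian collimator-detector response, `R_l` a
Gaussian-interpolation rotation operator, and `τ_l` the per-angle (and
per-bin) acquisition time. The multiplicative EM update

    f ← f / (Σ_{l∈S} H_lᵀ 1) · Σ_{l∈S} H_lᵀ ( g_l / max(H_l f, ε) )

then reconstructs every ECG bin on a common counts-per-second scale, so the
short last bin is automatically restored to the level of the others.

Around the reconstruction the package provides the full evaluation chain:
a beating short-axis LV phantom with programmable regional contraction
delays, an R-R simulator with controllable variability, fixed forward
gating (acceptance window, acquisition-time maps, list-mode event binning,
last-bin thinning to target activity ratios), first-Fourier-harmonic phase
analysis, Lin's concordance correlation coefficient (CCC), and desk-scale
population experiments.

## Worked example

Simulate one subject with moderate HRV, reconstruct both ways, compare:

```r
library(gatedSPECT)

spec  <- lvPhantomSpec()                      # 48x48x16, 4 mm, 6 sectors
osem  <- systemModel(mode = "osem")           # 32 angles over 180 deg
tosem <- systemModel(mode = "tosem")
beats <- generateRRSeries(0.9, 0.03 * 0.9, 32 * 10 + 2, seed = 3)
sim   <- simulateGatedSinogram(spec, beats, osem, gateConfig(),
                               dwellTime = 10, seed = 4)

so <- reconstructSeries(sim$sinogram, NULL,    osem,  reconConfig())
st <- reconstructSeries(sim$sinogram, sim$tau, tosem, reconConfig())
round(binTotals(so))   # 8552 8773 9319 9787 9667 9178 8807 7624
round(binTotals(st))   # 5255 5389 5746 6029 5963 5416 5270 ... (flat)

activityRatio(postprocessSeries(so, 1))        # ~74: OSEM last-bin dimming
```

The OSEM bin totals dip in the eighth bin (the HRV data shortage; the
activity ratio — last-bin total over the mean of bins 1–5 — is well below
100%), while the TOSEM totals stay level bin to bin because the shorter
acquisition time of the last bin is part of its system model.

Phase analysis of a delayed-contraction phantom:

```r
spec <- lvPhantomSpec(sectorDelay = c(0, 0, 45, 0, 0, 0))
# ... simulate and TOSEM-reconstruct as above, then:
grid <- midWallSamplingGrid(spec)
res  <- phaseAnalysis(postprocessSeries(st, 1, mask), grid)
res
#> PhaseAnalysisResult: 410 phases; BW 45.0 deg, StD 11.01 deg, ENT 62.71%
```

BW/StD/ENT summarize the spread of per-point contraction phases; wider
histograms mean more dyssynchrony.

A command-line front end wrapping these functions is installed at
`system.file("scripts", "gatedspect.R", package = "gatedSPECT")` with
`simulate`, `gate`, `reconstruct`, `phase` and `experiment` subcommands.

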