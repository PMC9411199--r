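---
title: "Methods: long-term VNC imaging analysis with flyvnc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: long-term VNC imaging analysis with flyvnc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flyvnc)
```

# Scope

`flyvnc` implements the computational analyses used with chronic two-photon
recordings of the *Drosophila* ventral nerve cord (VNC) and cervical
connective: two-channel motion correction, illumination correction and
pixel-wise dF/F, spherical-treadmill sensor processing and stationary-period
classification, statistics and peak-time mapping for caffeine-induced
activity waves, optogenetically evoked backward-walking metrics from arena
trajectories, and longitudinal quantification of mechanosensory axon
degradation after leg amputation. Because microscope data of this kind are
large and external, the package ships a first-class synthetic-data module
that generates every input modality with known ground truth; all validation
is against that truth.

# Motion correction

Recordings of the cervical connective suffer large inter-frame translations
plus smaller non-rigid deformations, and the calcium indicator (GCaMP6f) is
too dim and activity-dependent to register on. Motion is therefore estimated
on the co-expressed anatomical channel (tdTomato) and the identical
correction is applied to both channels (`correctTwoChannel()`).

The stages are:

1. **Center-of-mass pre-alignment** (`centerOfMassRegister()`): each frame
   is shifted by an integer number of pixels so its intensity center of
   mass matches the reference frame (the first recorded frame by default).
   The COM is computed on the frame minus its median, clipped at zero: on
   real PMT data with a dark background this equals the plain intensity
   COM, while on data with a bright uniform background offset the plain COM
   would recover only a fraction of the true translation. Integer shifts
   zero-fill the edges; the background margin is subsequently cropped
   (`cropCenter()`, e.g. 480 x 736 to 352 x 576 at acquisition scale),
   which also removes those bands.
2. **Variational optic flow** (`estimateMotionField()`): a dense
   displacement field minimizes a classical quadratic energy — a linearized
   brightness-constancy data term plus `lambdaSmooth` (default 800) times
   the squared gradient of the field. The solver runs coarse-to-fine over
   an image pyramid (3 levels, downscale 2) with three linearizations
   (warps) per level and up to 50 exact per-pixel 2x2 block Gauss-Seidel
   sweeps per linearization (tolerance 1e-3 px mean change per sweep).
   Block coordinate descent on a convex quadratic makes the energy
   non-increasing within each linearization, a property the test suite
   asserts. Images are rescaled to a 0-255 intensity range internally so
   the meaning of `lambdaSmooth` does not depend on detector gain.
3. **Bilinear warping** (`warpBilinear()`): fields are stored in the
   correction convention, `corrected(p) = frame(p + field(p))`, and both
   channels are resampled bilinearly with edge clamping.

Fields recovered on synthetic movies with up to 5 px rigid plus 2 px
non-rigid motion and noise at a few percent of the signal peak have a mean
endpoint error of about 0.35 px over the central analysis region
(`meanEndpointError()`, which excludes a 12 px border for the reason given
above); inside the axon ROIs the error is about 0.16 px.

For longitudinal projection series, translation-only registration
(`registerTranslation()`) suffices: the integer peak of a Hann-windowed FFT
cross-correlation is refined to subpixel precision by directly minimizing
the residual of the back-shifted image on successively finer grids (final
step 0.01 px).

# Illumination correction and dF/F

Fluorescence falls off along the medial-lateral (x) axis because thoracic
organs displaced by the implant scatter light. `fitIlluminationProfile()`
median-filters the temporal-mean image with a (71, 91) kernel and smooths
it with a Gaussian (sigma 3 px) to remove individual neurons, averages over
y, and fits a straight line to the most central 200 columns;
`applyIlluminationCorrection()` multiplies each column by the inverse of
that line. The correction aids visualization only: dF/F is invariant to it
because the signal and baseline of a pixel are multiplied by the same
factor, and the test suite checks this identity to 1e-6.

The baseline F0 (`computeBaseline()`) smooths each trial spatially
(Gaussian, sigma 10 px) and temporally (centered 10-sample boxcar, about
0.6 s at 16 Hz; edge windows are truncated and renormalized — whether the
original window was centered or causal is not stated, and centered is the
symmetric choice) and takes the per-pixel minimum across all frames of all
trials. F0 is floored at `1e-6` times the global intensity maximum so the
ratio `(F - F0) / F0` (`computeDff()`) is always defined; dF/F is bounded
below by -1.

`temporalDenoise()` stands in for the interpolation-network denoiser used
on the original data: each interior frame is predicted per pixel from the
30 frames before and after it (the frame itself excluded) by local linear
regression on time. With this symmetric design the prediction equals the
neighborhood mean, which removes temporally independent noise (variance
reduced to 1/60) and retains slow dynamics; border frames are returned
unmodified and flagged. No trained weights are involved.

# Treadmill processing and synchronization

Optic-flow sensor readings are intrinsically noisy and are smoothed with a
centered 80-sample moving average (about 200 ms at 400 Hz,
`movingAverage()`). `sensorsToVelocities()` converts the two-sensor
readings to body-frame forward/sideways/turning rotation rates with a
fixed, documented linear map for two sensors viewing the ball equator at
+-45 degrees azimuth (the original sensor geometry is described elsewhere;
this map is a design choice, and the synthetic generator uses the same
forward model so round trips are exact). Rates in rotations/s convert to
surface speed as `pi * diameter`, so the classification threshold of
0.01 rotations/s on a 10 mm ball equals 0.31 mm/s.

A sample is stationary (`classifyStationary()`) iff all three absolute
rates are below threshold and at least 75% of the samples within +-0.5 s
also are; the context criterion removes brief pauses between walking
bouts. Edge windows use the available samples only. All modalities are
synchronized by averaging the samples acquired during each two-photon
frame (`downsampleToFrames()`; boolean signals use a majority vote, a
choice the original description leaves open).

# Caffeine-wave statistics and peak-time maps

Connective-mean fluorescence traces are normalized per fly to the 99th
percentile of the concatenated pre-feeding trials (`computeNormalization()`;
percentiles use the linear-interpolation definition throughout). The
"maximum" activity of a period (`maxNormalizedActivity()`) is the upper
boundary of the 99% percentile of the normalized trace — by construction
the pre-feeding maximum is exactly unity for every fly. Concatenation
(rather than averaging per-trial percentiles) was an open choice; it makes
the self-normalization identity exact.

Group comparisons use the Mann-Whitney U test (`mannWhitneyU()`) with two
methods: a tie-corrected, continuity-corrected normal approximation — at
n = 3 vs 3 under complete separation this gives p = 0.0404, matching the
printed one-sided p = 0.040, which is why it is the default — and exact
enumeration of the permutation null for group sizes up to 8 (at 3 vs 3 the
exact one-sided p under separation is 1/20 = 0.05). In the synthetic
caffeine experiment a period is declared significant when the high-caffeine
group exceeds both controls at p < 0.05, mirroring the two reported
comparisons.

Wave timing is mapped by finding the time of peak connective-mean
fluorescence (`globalPeakTime()`, ties broken earliest) and then, per
pixel, the maximum of the temporally (sigma 10 samples, ~0.62 s) and
spatially (sigma 1 px) smoothed signal within +-10 s of that peak
(`pixelPeakTimeMap()`). On synthetic traveling waves the per-ROI median
peak times recover the generated region order (dorsomedial, dorsolateral,
ventral, giant fiber) with Spearman rank correlation above 0.99 in the
noise-free case.

# Arena locomotion metrics

Signed translational velocity is the first Savitzky-Golay derivative
(order 2) of the tracked centroid, with the sign set negative for motion
counter to the heading (`translationalVelocity()`). The window length is
not specified by the protocol description; the default is 15 frames
(187.5 ms at 80 fps), and order-2 differentiation is exact on quadratic
motion. Epochs with more than 0.3 s of cumulative wall contact (strictly
more: exactly 0.3 s is kept) or any dorsally flipped frame are excluded
(`excludeEpochs()`). The three metrics per 3 s stimulation epoch are the
response slope (acceleration from onset to the velocity minimum; 0 with a
warning if the minimum is at the onset), the backward distance (left
Riemann sum over frames with negative velocity), and the maximum backward
speed (the plain epoch minimum) — see `responseSlope()`,
`backwardDistance()`, `maxNegativeVelocity()`. The default session is 30 s
spontaneous plus three 3 s stimulations with 10 s intervals: 59 s.

# Longitudinal degradation

Daily projections are registered to day 1 by translation (`alignSeries()`;
the original workflow used a feature-based plugin, but the synthetic series
jitter only by translation, so a translation stand-in is sufficient and
documented as such). ROI means are extracted per day with day-1 ROI masks
propagated unchanged (`roiMeanByDay()`), normalized by the day-1 mean per
(fly, ROI) (`normalizeToFirstDay()`; per-fly normalization was chosen where
the original description is ambiguous), and the intact and amputated groups
are compared per day with the two-sided exact Mann-Whitney test
(`compareGroupsByDay()`). At 5 vs 5 under complete separation the exact
two-sided p is 2/252 = 0.0079.

# The synthetic-data module

`generateConnectiveMovie()` emulates coronal cross-sections of the
connective: elliptical axon cross-sections (truncated 2-D Gaussians,
truncation at 2.5 sigma) assigned to the four anatomical regions, on a dim
background carrying a static smoothed speckle texture (sd 8 a.u., sigma
2 px). The texture stands for structured tissue autofluorescence; a
perfectly flat background would make motion unobservable away from the
axons and is not what two-photon data look like. Motion is a rigid
sinusoidal translation plus a smooth non-rigid field built from at most
three coarse sinusoidal basis fields — deliberately within the
representational reach of a smoothness-regularized estimator — and is zero
on the first frame so that truth fields are relative to the recorded
reference. Truth motion fields are stored in the correction convention via
fixed-point inversion of the synthesis deformation, so endpoint-error
comparisons carry no inversion bias. The green channel scales each axon by
a calcium trace: baseline 1, smoothed Gaussian locomotor fluctuations
(sd 0.3 of baseline), and optionally a traveling wave (Gaussian bump,
amplitude 4x the fluctuation amplitude, 1 s inter-region lag by default)
sweeping the regions in a fixed order. A linear left-right gain and
additive Gaussian noise clipped at zero complete the model; the noise
model is a stated assumption, not something the imaging description
specifies.

`generateSensorTraces()` synthesizes raw sensor readings through the same
forward model the inverse map uses; `generateArenaTrajectory()` integrates
a smooth (half-cosine) transient velocity profile whose mean descent rate
equals the nominal response slope, with a relaxation twice as slow — a
plateau-shaped response would make the slope metric ill-posed (the argmin
drifts along a flat minimum), and a kinked profile biases the
Savitzky-Golay derivative; `generateDegradationSeries()` applies
exponential photobleaching to all ROIs and additional exponential decay to
the designated ROI of amputated flies from 2 dpi, with recorded day-to-day
translation jitter. Generator truth metrics are computed from the
noise-free sampled signals with the same discrete definitions the analysis
uses, which is what "ground truth" should mean for discretized metrics.

What the synthetic data do **not** emulate: photon (Poisson) noise,
slow focus drift, occlusions, z-motion, realistic axon morphology beyond
ellipses, behavioral video, and pose. Passing tests therefore demonstrate
correctness of the computations under the stated forward models, not
performance on arbitrary real recordings.

# Numerical choices and degenerate inputs

* Percentiles: linear interpolation (type 7) everywhere.
* Gaussian smoothing uses truncated kernels (radius 4 sigma) with
  renormalized weights at the edges; the median filter reflects at the
  borders.
* Even-width boxcars span offsets `-(w %/% 2)` to `(w - 1) %/% 2`.
* All-zero frames have no COM and pass through with a warning; constant
  images have no registrable translation and return (0, 0) with a warning;
  all-tied Mann-Whitney groups give p = 1 with a warning; a velocity
  minimum at the epoch onset gives slope 0 with a warning.
* F0 is floored at 1e-6 of the global maximum; zero-baseline handling is
  not specified by the original description.
* Ties in the global peak resolve to the earliest time.
* Reported problem sizes: the test suite exercises movies up to
  200 frames at 128 x 192 (the motion-recovery property), 25 s trials at
  48 x 72 for the nine-fly caffeine study, and 15-day series at 80 x 96
  for ten flies; the full acquisition scale (480 x 736) is supported
  through the same parameters.

# Known limitations

* The optic-flow solver is a classical quadratic model; it is validated by
  ground-truth recovery, not by equivalence to any specific prior solver.
* Translation-only alignment of longitudinal series cannot absorb rotation
  or scale changes between days.
* The temporal denoiser is linear; it will attenuate fast transients that
  a learned interpolator could preserve.
* The sensor geometry is a fixed documented convention; data from a rig
  with a different sensor placement need their own map.
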