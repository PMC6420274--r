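---
title: "Analysing VIPA Brillouin frames: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing VIPA Brillouin frames: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vipabrill)
```

## The measurement and its image model

A dual-stage crossed-VIPA spectrometer maps a Brillouin spectrum onto a
2-D detector. Adjacent diffraction orders form a square: the elastic
(Rayleigh) line appears at the four corners, saturating the detector and
blooming into horizontal and vertical streaks, and the inelastic doublet —
Stokes and anti-Stokes Brillouin peaks — lies along the main diagonal
between two adjacent Rayleigh spots. Because the Rayleigh peaks are
unavoidable in this optical layout, the package treats them as an asset:
they are the fiducial markers that make registration and frequency
calibration fully automatic, so slow laser drift and pattern distortion
never require operator intervention.

The analysis assumes:

* the diffraction-order curves can be approximated as straight lines over
  the selected square (the package warns when the detected quadrilateral's
  side-length ratio leaves [0.8, 1.25], where this approximation degrades);
* a *linear* relation between diagonal position and frequency, anchored
  only by the free spectral range (FSR) between the two Rayleigh
  positions — no nonlinear dispersion model is attempted;
* one Stokes and one anti-Stokes peak per inter-order segment, away from
  the Rayleigh skirts.

## Stage by stage

**Display enhancement.** `contrast_normalize()` maps counts through a
linear ramp clamped at `mu +/- alpha * sigma`. It exists purely so a human
can see the dim doublet next to saturated streaks; `process_frame()` never
calls it, and a test asserts results are identical whether or not a frame
was rendered. The mean and standard deviation are taken over the whole
frame — the saturated structure inflates sigma slightly, but since the
output is cosmetic this is harmless and keeps the operation parameter-free.
`alpha` defaults to 0.5, the middle of its admissible range.

**Corner localization.** After a Gaussian denoise (default sigma 1 px) and
a threshold at 0.95 of the frame maximum, only saturated structure
survives. Each column of the mask is scanned for runs of `TRUE` pixels
(and each row, for the vertical streaks); run centres are points on the
streak lines. An adaptive filter drops runs longer than
`max(5, 2.5 * median)` — those are the perpendicular streak seen end-on,
or corner blobs merged with a streak. The mask's centre of gravity splits
the points into quadrants; per corner, a horizontal and a vertical
least-squares line are fitted and intersected, and the intersection is
refined by the intensity-weighted centre of gravity (WCoG) of the *raw*
frame over a square window, re-centred iteratively until stable.

Two design choices deserve notes. Saturated pixels enter the WCoG as-is:
the plateau of a clipped symmetric spot is itself symmetric, so no bias
results, and masking it would discard most of the signal. The refinement
window half-width defaults to 8 px: empirically, localization error falls
monotonically as the window grows from 3 to 8 px, because thresholded run
centres are quantized to half-pixels and a larger window averages that
quantization out; beyond the spot-plus-streak neighbourhood there is
nothing left to gain and other structure would leak in.

**Registration.** `compute_transform()` solves the exact four-point
homography (8 degrees of freedom) mapping the detected corners onto a
canonical square; an affine-restricted mode (6 dof, least squares over the
four correspondences) is available when drift is known to be affine. The
full homography is the default because it is exact for four points and
degrades to the affine solution when the distortion is affine.
`warp_frame()` resamples by inverse mapping with bilinear interpolation,
zero-filling outside the source; source coordinates within 1e-9 px of an
integer are snapped so that identity and integer-shift transforms
reproduce pixel values bit-exactly.

**Spectral extraction.** The band of half-width 10 px around the
top-left→bottom-right diagonal is resampled so the dispersion axis runs
along columns, and each channel takes its column maximum — robust to small
perpendicular misalignment of the ridge, and insensitive to row
permutations within the band. For the quantitative chain,
`process_frame()` composes the band geometry with the *inverse* homography
and samples the raw frame once with a Catmull-Rom cubic kernel, rather
than re-interpolating the already-warped raster: resampling twice with
bilinear kernels broadens an ~11-px-FWHM Lorentzian by several percent and
caps the achievable fit R² near 0.992, while the single-pass cubic path
keeps noiseless round-trip errors below 0.2% and R² above 0.999. The
warped raster is still produced for display and QC.

**Calibration.** `nu(i) = fsr * min(i - r0, r1 - i) / (r1 - r0)`, with
`r0`, `r1` taken from the registered corner positions projected onto the
band axis (not re-estimated from the 1-D trace, keeping calibration
consistent with registration). The fold at the midpoint converts both
sides to positive shifts; the anti-Stokes branch therefore runs high-to-low
in frequency, and fits sort by frequency first.

**Segmentation.** A channel is signal when it exceeds `k` times the mean
of the surrounding `2 * window_halfwidth` channels (centre excluded);
`k = 1` by default — the threshold *is* the local average, the only
preselected quantity in the chain. Channels within `exclusion` of either
Rayleigh position are masked first. The exclusion default resolves to
`band_halfwidth + 5`: a band of half-width `h` geometrically intersects
the 45°-oblique saturated streaks within `h` channels of either end, so
any exclusion smaller than `h` admits saturated end segments that dwarf
the Brillouin peaks. With noise, many 1–2-channel spurious segments appear
(any channel above its local mean qualifies); they are harmless because
the per-side candidate is chosen by apex intensity and short segments are
never fitted.

**Fitting.** FWHM-parameterized Lorentzian and Gaussian models with
additive offset, so "linewidth" always means FWHM in GHz. Starting values
are moment-based (apex position/height, half-maximum crossings, edge-mean
offset); bounds keep amplitude positive, the centre inside the segment and
the width inside `(0, fsr/2]`, preventing collapse onto negative peaks.
The optimizer is Levenberg–Marquardt (`minpack.lm`), 200 iterations,
relative tolerance 1e-8. Detected segments cover only the peak core, so
`process_frame()` pads each fitted segment by `fit_pad = 15` channels of
baseline wings (clipped at the exclusion zone and at the fold midpoint);
without wings the width estimate inherits an ~2% bias from the core-only
window, with them it drops to ~0.15%. Non-convergence is reported, not
raised: the result carries `converged = FALSE` and the side combination
falls back to the converged side with a QC flag. Fitted widths are
*apparent* widths — no deconvolution of the ~0.6 GHz instrument function
is attempted. Stokes and anti-Stokes estimates are averaged (their
absolute difference is kept as a QC asymmetry metric) since neither side
is physically preferred at these shifts.

## The synthetic generator

`generate_frame()` renders, in order: a constant background; four
blooming streak lines through the corner pairs (amplitude 2.5× the
saturation level with 1.5 px Gaussian cross-section, clipped — giving the
flat-topped, fully saturated lines a few pixels wide that real sCMOS
blooming produces; a 1-px streak *at* clip level would vanish from the
0.95-threshold mask after the pipeline's own denoise step); four Rayleigh
spots (2-D Gaussians, sigma 2 px, amplitude 200 000 counts clipped at
65 535); and the Brillouin doublet as Lorentzian ridges along the diagonal
with 1.5 px Gaussian cross-section, at arc-length fractions
`shift / fsr` and `1 - shift / fsr` — so applying the calibration to the
generator's own peak positions returns the configured shift to machine
precision. Drift is applied to the *geometry* (corners, lines, diagonal),
keeping sub-pixel ground truth exact. Clipping precedes additive Gaussian
noise; the seed makes frames bit-reproducible without touching the
session RNG.

Detector counts are package assumptions (the background of 100 counts,
Brillouin amplitude of 800 counts and the amplitude ratios are not
dictated by any instrument): they are chosen so that Rayleigh light
saturates a 16-bit detector while the doublet stays three orders of
magnitude below it, as in typical 1–4 s exposures. "Peak SNR" throughout
means `brillouin_amplitude / noise_sigma`. The presets carry literature
shift/linewidth pairs for the two standard calibration liquids — methanol
(5.6 GHz, 0.7 GHz) and water (7.5 GHz, 0.65 GHz) at 532 nm — plus a
configurable collagen-gel preset (default 8 GHz, admissible 7–9 GHz).

What the generator does **not** emulate: Poisson photon statistics and
fixed-pattern noise (noise is additive Gaussian with controllable
variance — sufficient to exercise thresholding, segmentation and fitting,
but a real camera's noise is signal-dependent); curvature of the
diffraction orders (orders are straight lines, matching the analysis
assumption rather than challenging it); cosmic rays and hot pixels;
inter-order leakage beyond one Stokes/anti-Stokes pair. Passing the
round-trip suites therefore demonstrates correctness of the *algorithms*
under the stated image model, not robustness to every real-world artefact.

## Degenerate inputs and failure policy

Constant frames are rejected by `contrast_normalize()` (a diagnostic of
acquisition failure, not a displayable image). Blank or structure-free
masks, collinear centre pixels, parallel fitted lines and non-invertible
transforms raise errors naming the failed stage; `process_frames()`
catches per-frame failures and records them as missing map positions with
the failure reason, so a long scan survives isolated bad frames.
Duplicated stage positions are an error at map assembly.

## Problem sizes used in validation

The test and acceptance suites run on 480×480 frames (canonical square
side 359 px, diagonal ≈ 508 channels, ~0.06 GHz per channel at
FSR 30 GHz): round-trip means over 20 drifted frames per liquid at peak
SNR 50; registration statistics over 100 drifted fixtures at peak SNR 20;
model-discrimination and estimator-consistency checks over 100
spectrum-level replicates. These sizes give stable statistics for the
sub-pixel and sub-0.1-GHz tolerances being verified while keeping the
whole suite quick to run on a laptop.

## Known limitations

* Linear dispersion only; instruments with visibly curved orders need a
  nonlinear calibration this package does not provide.
* Shift and width are apparent values convolved with the instrument
  function; comparisons across spectrometers require a deconvolution step
  out of scope here.
* The corner-based calibration assumes the selected square is bounded by
  four resolvable Rayleigh peaks; optical Rayleigh suppression would
  remove the fiducials this method relies on.
* No tracking of corners across a time series: each frame is registered
  independently (the per-frame drift record enables external QC).
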