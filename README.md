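# vipabrill

Automated analysis of VIPA Brillouin spectrometer images in R.

Brillouin light scattering (BLS) microscopy probes the viscoelasticity of
biological samples through thermally excited acoustic waves in the GHz
range: the Brillouin frequency shift reports acoustic velocity (hence
stiffness), the linewidth reports acoustic attenuation. A dual-stage
crossed-VIPA (virtually imaged phase array) spectrometer disperses each
spectrum onto a 2-D detector frame as a square pattern: elastically
scattered Rayleigh light saturates the detector at the four corners (and
along blooming streaks through them), while the Stokes and anti-Stokes
Brillouin doublet sits on the main diagonal. `vipabrill` turns such raw
frames into calibrated shift/linewidth values and hyperspectral stiffness
maps, for anyone running or simulating a VIPA Brillouin microscope.

## The method

For each frame the pipeline runs:

1. **Display enhancement** (optional, never feeds the analysis):
   `I' = clamp((I − μ + ασ) / (2ασ), 0, 1)` with frame mean μ, standard
   deviation σ, and contrast constant α ∈ (0, 1].
2. **Rayleigh-corner localization**: Gaussian denoise → threshold at 0.95
   of the frame maximum → centre pixels of the saturated streak runs →
   per-corner horizontal/vertical least-squares lines → intersections →
   intensity-weighted centre-of-gravity refinement on the raw frame.
3. **Drift correction**: exact four-point homography mapping the detected
   corners onto a canonical square, applied by inverse-mapped resampling.
4. **Spectral extraction**: the band around the top-left → bottom-right
   diagonal is rotated onto the x-axis and each channel takes the maximum
   intensity of its column.
5. **Frequency calibration** from the free spectral range (FSR) between
   the bounding Rayleigh positions R₀, R₁:
   `ν_B(i) = FSR · min(i − R₀, R₁ − i) / (R₁ − R₀)`,
   folding Stokes and anti-Stokes onto a common positive-shift axis.
6. **Peak segmentation**: channels exceeding the local-average intensity
   form candidate segments; Rayleigh skirts are excluded.
7. **Line-shape fitting**: Lorentzian (or Gaussian)
   `A (Γ/2)² / ((ν − ν₀)² + (Γ/2)²) + c` by bounded Levenberg–Marquardt
   least squares, reporting shift ν₀, FWHM Γ, RMS and R²; Stokes and
   anti-Stokes results are averaged and their difference kept as a QC
   metric.

A synthetic frame generator (`vipa_preset()`, `generate_frame()`) renders
the full pattern — clipped Rayleigh spots, saturated streaks, Lorentzian
doublet, Gaussian noise, affine drift — with exact ground truth, so every
stage is testable without instrument data. `estimate_modulus()` converts a
shift to a longitudinal modulus `M = ρ (λ ν_B / 2n)²`.

## Worked example

```r
library(vipabrill)

set.seed(42)
truth <- vipa_preset("water", snr = 50, seed = 42,
                     distortion = random_drift(5, 0.02, centre = c(240, 240)))
frame  <- generate_frame(truth)               # 480x480 counts matrix
result <- process_frame(frame, pipeline_config(fsr = 30))
result
#> <frame_result>
#>   shift: 7.494 GHz   FWHM: 0.6557 GHz
#>   R^2: 0.9976   RMS: 11.23 counts
#>   segments: 92   drift (tl, px): -5.06/0.08
result$fits$stokes
#> <peak_fit> lorentzian, stokes side: centre 7.497 GHz, FWHM 0.6573 GHz
#>   R^2 0.99765, RMS 11.13 over 41 channels (converged)
estimate_modulus(result$combined$shift, refractive_index = 1.33,
                 mass_density = 998, wavelength_nm = 532)
#> [1] 2.241641
```

The frame was generated from the water preset (literature shift 7.5 GHz,
linewidth 0.65 GHz) with a random ≤ 5 px drift and peak SNR 50; the
pipeline localizes the drifted corners, registers the pattern and recovers
7.494 GHz / 0.656 GHz — within a few mGHz of the injected truth. The
modulus value is the GPa-scale longitudinal modulus of water-like material
at 532 nm. `process_frames()` + a manifest of stage positions produce a
per-position map (`x_um, y_um, shift_ghz, fwhm_ghz, r_squared, rms,
qc_flags`).

A command-line front end lives at `inst/cli/vipa-brill.R`:

```sh
Rscript inst/cli/vipa-brill.R simulate --preset methanol --snr 50 \
    --seed 3 --drift 4 --out frame.tiff --truth truth.json
Rscript inst/cli/vipa-brill.R process frame.tiff --out result.json
```

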