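# Shared helpers: small fixtures and independent oracles.

# Noiseless, undistorted truth for a preset.
quiet_truth <- function(preset = "water", ...) {
  vipa_preset(preset, snr = Inf, ...)
}

# Independent brute-force oracle: intensity-weighted centroid over an
# exhaustive window centred on a given position. Deliberately written as a
# plain double loop, sharing no code with refine_corner().
wcog_oracle <- function(frame, centre, halfwidth) {
  r0 <- round(centre[1])
  c0 <- round(centre[2])
  sw <- 0
  sr <- 0
  sc <- 0
  for (r in (r0 - halfwidth):(r0 + halfwidth)) {
    for (c in (c0 - halfwidth):(c0 + halfwidth)) {
      w <- frame[r, c]
      sw <- sw + w
      sr <- sr + w * r
      sc <- sc + w * c
    }
  }
  c(sr / sw, sc / sw)
}

# 1-D synthetic calibrated spectrum: Lorentzian doublet on the canonical
# frequency axis, optionally noisy. Used for spectrum-level fitting tests
# without running the imaging chain.
synth_doublet_spectrum <- function(shift = 7.5, fwhm = 0.65, amplitude = 800,
                                   background = 100, noise_sigma = 0,
                                   fsr = 30, n_channels = 510,
                                   r1 = 509.117) {
  channels <- 0:(n_channels - 1)
  nu <- channel_frequency(channels, 0, r1, fsr)
  # the folded axis renders both Stokes and anti-Stokes at +shift
  y <- lorentzian(nu, amplitude, shift, fwhm, background)
  if (noise_sigma > 0) y <- y + rnorm(length(y), 0, noise_sigma)
  structure(
    list(intensities = y, channels = channels, r0 = 0, r1 = r1,
         frequencies = nu, fsr = fsr),
    class = c("calibrated_spectrum", "brillouin_spectrum")
  )
}

# Corner localization error (px) of one frame against its generator truth.
corner_errors <- function(frame, truth, config = pipeline_config()) {
  den <- denoise_frame(frame, config$denoise_sigma)
  cs <- locate_corners(binarize_frame(den, config$binarize_fraction),
                       frame, config$refine_halfwidth)
  sqrt(rowSums((cs$corners - true_corners(truth))^2))
}
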