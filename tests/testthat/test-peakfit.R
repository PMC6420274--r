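test_that("line-shape closed forms: apex, half maximum, symmetry, area", {
  for (f in list(lorentzian, gaussian_peak)) {
    expect_equal(f(7.5, 100, 7.5, 0.65, 10), 110)
    expect_equal(f(7.5 + 0.325, 100, 7.5, 0.65, 10), 60)
    expect_equal(f(7.5 - 0.325, 100, 7.5, 0.65, 10), 60)
    x <- seq(-2, 2, by = 0.37)
    expect_equal(f(7.5 + x, 100, 7.5, 0.65, 10), f(7.5 - x, 100, 7.5, 0.65, 10))
  }
  # Gaussian area: A * fwhm * sqrt(pi / (4 ln 2))
  area <- integrate(gaussian_peak, -Inf, Inf, amplitude = 3, centre = 1,
                    fwhm = 0.8, offset = 0)$value
  expect_equal(area, 3 * 0.8 * sqrt(pi / (4 * log(2))), tolerance = 1e-6)
})

test_that("each model recovers its own noiseless samples exactly", {
  nu_all <- channel_frequency(0:509, 0, 509.117, 30)
  sel <- nu_all >= 6 & nu_all <= 9 & 0:509 < 255
  truth_pars <- c(amplitude = 100, centre = 7.5, fwhm = 0.65, offset = 10)
  for (kind in c("lorentzian", "gaussian")) {
    f <- if (kind == "lorentzian") lorentzian else gaussian_peak
    spec <- structure(
      list(intensities = f(nu_all, 100, 7.5, 0.65, 10),
           channels = 0:509, r0 = 0, r1 = 509.117,
           frequencies = nu_all, fsr = 30),
      class = c("calibrated_spectrum", "brillouin_spectrum")
    )
    seg <- list(start = min((0:509)[sel]), end = max((0:509)[sel]),
                side = "stokes")
    fit <- fit_peak(spec, seg, kind = kind)
    expect_true(fit$converged)
    expect_lt(max(abs(fit$parameters - truth_pars) / truth_pars), 1e-6)
    expect_equal(fit$r_squared, 1, tolerance = 1e-9)
    expect_lt(fit$rms, 1e-6)
    expect_equal(fit$n_channels, sum(sel))
  }
})

test_that("a too-short segment is rejected", {
  spec <- synth_doublet_spectrum()
  expect_error(fit_peak(spec, list(start = 100, end = 103)), "too short")
})

test_that("Lorentzian data are fitted better by the Lorentzian model", {
  spec <- synth_doublet_spectrum(noise_sigma = 0)
  seg <- segment_peaks(spec, 10, exclusion = 15)
  seg <- seg[seg$side == "stokes", ][1, ]
  seg$start <- seg$start - 15
  seg$end <- seg$end + 15
  fl <- fit_peak(spec, seg, "lorentzian")
  fg <- fit_peak(spec, seg, "gaussian")
  expect_gt(fl$r_squared, fg$r_squared)
  expect_gt(fl$r_squared, 0.999)
})

test_that("shift estimates are unbiased over noisy replicates", {
  set.seed(99)
  biases <- replicate(100, {
    spec <- synth_doublet_spectrum(shift = 7.5, fwhm = 0.65, amplitude = 800,
                                   noise_sigma = 16)  # peak SNR 50
    segs <- segment_peaks(spec, 10, exclusion = 15)
    segs <- segs[segs$side == "stokes", , drop = FALSE]
    seg <- segs[which.max(segs$apex_intensity), ]
    seg$start <- seg$start - 15
    seg$end <- seg$end + 15
    fit_peak(spec, seg)$shift - 7.5
  })
  expect_lt(abs(mean(biases)), 0.05)
})

test_that("shift RMSE shrinks as SNR grows", {
  set.seed(1234)
  rmse <- vapply(c(10, 20, 50), function(snr) {
    errs <- replicate(40, {
      spec <- synth_doublet_spectrum(amplitude = 800,
                                     noise_sigma = 800 / snr)
      segs <- segment_peaks(spec, 10, exclusion = 15)
      segs <- segs[segs$side == "stokes", , drop = FALSE]
      seg <- segs[which.max(segs$apex_intensity), ]
      seg$start <- seg$start - 15
      seg$end <- seg$end + 15
      fit_peak(spec, seg)$shift - 7.5
    })
    sqrt(mean(errs^2))
  }, numeric(1))
  expect_true(all(diff(rmse) < 0))
})

test_that("side combination averages, reports asymmetry and falls back", {
  mk <- function(shift, fwhm, conv = TRUE) {
    structure(list(shift = shift, fwhm = fwhm, converged = conv,
                   r_squared = 0.99, rms = 1), class = "peak_fit")
  }
  same <- combine_sides(mk(7.5, 0.6), mk(7.5, 0.6))
  expect_equal(same$shift, 7.5)
  expect_equal(same$asymmetry_shift, 0)
  expect_length(same$qc_flags, 0)

  cb <- combine_sides(mk(7.4, 0.6), mk(7.6, 0.7))
  expect_equal(cb$shift, 7.5)
  expect_equal(cb$fwhm, 0.65)
  expect_equal(cb$asymmetry_shift, 0.2)

  fb <- combine_sides(mk(7.4, 0.6), mk(7.6, 0.7, conv = FALSE))
  expect_equal(fb$shift, 7.4)
  expect_true("antistokes_unconverged" %in% fb$qc_flags)

  none <- combine_sides(mk(7.4, 0.6, FALSE), NULL)
  expect_true(is.na(none$shift))
  expect_true("no_converged_side" %in% none$qc_flags)
})
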