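test_that("band extraction turns the diagonal into the x-axis", {
  # a ridge along the tl->br diagonal of a small canonical frame
  n <- 61
  fr <- matrix(0, n, n)
  for (k in 1:n) fr[k, k] <- 100
  can <- rbind(tl = c(6, 6), tr = c(6, 56), br = c(56, 56), bl = c(56, 6))
  band <- extract_band(fr, can, band_halfwidth = 3)
  expect_s3_class(band, "spectral_band")
  # the central offset row carries the ridge
  mid_row <- which(band$offsets == 0)
  expect_equal(which.max(rowSums(band$band)), mid_row)
  expect_equal(band$r0, 0)
  expect_equal(band$r1, 50 * sqrt(2), tolerance = 1e-12)
})

test_that("Rayleigh maxima bound the band of a canonical fixture", {
  truth <- quiet_truth("water")
  fr <- generate_frame(truth)
  band <- extract_band(fr, truth$corners, band_halfwidth = 10)
  spec <- project_max(band)
  n <- length(spec$intensities)
  # saturated ends, quiet middle
  expect_gt(spec$intensities[1], 0.9 * truth$saturation_level)
  expect_gt(spec$intensities[n], 0.9 * truth$saturation_level)
  expect_lt(max(spec$intensities[(n %/% 2 - 20):(n %/% 2 + 20)]),
            0.1 * truth$saturation_level)
})

test_that("an oversized band is rejected", {
  fr <- matrix(0, 61, 61)
  can <- rbind(c(6, 6), c(6, 56), c(56, 56), c(56, 6))
  expect_error(extract_band(fr, can, band_halfwidth = 30), "band exceeds")
})

test_that("maximum projection takes the column-wise maximum", {
  m <- matrix(c(1, 5, 2,
                9, 3, 4), 2, 3, byrow = TRUE)
  spec <- project_max(m)
  expect_equal(spec$intensities, c(9, 5, 4))
  # permuting rows changes nothing
  expect_equal(project_max(m[c(2, 1), ])$intensities, spec$intensities)
})

test_that("the calibration matches its closed form", {
  expect_equal(channel_frequency(100, 100, 500, 30), 0)
  expect_equal(channel_frequency(300, 100, 500, 30), 15)
  expect_equal(channel_frequency(200, 100, 500, 30), 7.5)
  expect_error(channel_frequency(1, 5, 5, 30), "r0")
  expect_error(channel_frequency(1, 0, 10, -1), "fsr")
})

test_that("calibration is symmetric about the midpoint with max fsr/2", {
  r0 <- 3.2
  r1 <- 509.7
  i <- seq(ceiling(r0), floor(r1))
  nu <- channel_frequency(i, r0, r1, 30)
  nu_mirror <- channel_frequency(r0 + r1 - i, r0, r1, 30)
  expect_equal(nu, nu_mirror, tolerance = 1e-12)
  expect_true(all(nu >= 0 & nu <= 15))
  expect_equal(channel_frequency((r0 + r1) / 2, r0, r1, 30), 15)
})

test_that("fixture spectra peak at the generator's configured positions", {
  truth <- quiet_truth("water")
  res <- process_frame(generate_frame(truth))
  segs <- res$segments[order(-res$segments$apex_intensity), ][1:2, ]
  pos <- true_peak_positions(truth)
  # generator positions are arc lengths on the distorted frame; identity
  # distortion means they transfer directly to the canonical band axis
  expect_lt(abs(min(segs$apex) - pos[["stokes"]]), 1)
  expect_lt(abs(max(segs$apex) - pos[["antistokes"]]), 1)
})

test_that("peak segmentation behaves on degenerate spectra", {
  flat <- project_max(matrix(7, 3, 60))
  expect_equal(nrow(segment_peaks(flat, 10, exclusion = 0)), 0)
  spike <- matrix(1, 1, 60)
  spike[30] <- 50
  s <- segment_peaks(project_max(spike), 10, exclusion = 0)
  expect_equal(nrow(s), 1)
  expect_equal(s$apex, 29)  # 0-based channel of the spike
  expect_equal(s$n_channels, 1)
  expect_error(segment_peaks(project_max(matrix(1, 1, 5)), 10), "shorter")
})

test_that("noiseless water spectra yield exactly two disjoint segments", {
  truth <- quiet_truth("water")
  res <- process_frame(generate_frame(truth))
  cfg <- pipeline_config()
  segs <- segment_peaks(res$spectrum, cfg$segment_window,
                        cfg$segment_exclusion)
  expect_equal(nrow(segs), 2)
  expect_setequal(segs$side, c("stokes", "antistokes"))
  expect_lt(segs$end[1], segs$start[2])  # disjoint
  pos <- true_peak_positions(truth)
  expect_true(segs$start[1] <= pos[["stokes"]] &&
                pos[["stokes"]] <= segs$end[1])
  expect_true(segs$start[2] <= pos[["antistokes"]] &&
                pos[["antistokes"]] <= segs$end[2])
})

test_that("enlarging the exclusion never adds segments", {
  set.seed(5)
  truth <- vipa_preset("water", snr = 20, seed = 5)
  res <- process_frame(generate_frame(truth))
  counts <- vapply(c(15, 25, 40, 80, 150), function(excl) {
    nrow(segment_peaks(res$spectrum, 10, exclusion = excl))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})
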