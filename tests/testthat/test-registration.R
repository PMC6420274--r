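test_that("denoise is the identity at sigma 0 and conserves an impulse", {
  fr <- matrix(rnorm(100), 10, 10)
  expect_identical(denoise_frame(fr, 0), fr)
  imp <- matrix(0, 31, 31)
  imp[16, 16] <- 100
  sm <- denoise_frame(imp, 1)
  expect_equal(sum(sm), 100, tolerance = 1e-6)
  expect_lt(max(sm), 100)
  expect_equal(which.max(sm), which.max(imp))
})

test_that("denoising reduces per-pixel noise variance", {
  set.seed(7)
  worse <- 0
  for (i in 1:20) {
    fr <- matrix(rnorm(64 * 64, 100, 10), 64, 64)
    if (var(as.vector(denoise_frame(fr, 1))) >= var(as.vector(fr))) {
      worse <- worse + 1
    }
  }
  expect_equal(worse, 0)
})

test_that("binarize thresholds at the stated fraction of the maximum", {
  fr <- matrix(c(949, 951, 1000, 0), 2, 2)
  m <- binarize_frame(fr, 0.95)
  expect_equal(as.vector(m), c(FALSE, TRUE, TRUE, FALSE))
  expect_true(all(binarize_frame(matrix(5, 3, 3), 0.95)))
  expect_error(binarize_frame(fr, 1), "fraction")
})

test_that("noiseless fixture mask covers only saturated structure", {
  truth <- quiet_truth("water")
  fr <- generate_frame(truth)
  mask <- binarize_frame(denoise_frame(fr, 1), 0.95)
  idx <- which(mask, arr.ind = TRUE)
  P <- true_corners(truth)
  # every mask pixel lies within a few px of a streak line (rows/cols of the
  # square) or a corner spot; Brillouin ridge and background never saturate
  near_line <- abs(idx[, 1] - P["tl", 1]) < 4 | abs(idx[, 1] - P["br", 1]) < 4 |
    abs(idx[, 2] - P["tl", 2]) < 4 | abs(idx[, 2] - P["br", 2]) < 4
  expect_true(all(near_line))
  expect_gt(nrow(idx), 100)
})

test_that("corners of a noiseless undistorted fixture are found sub-pixel", {
  truth <- quiet_truth("water")
  fr <- generate_frame(truth)
  errs <- corner_errors(fr, truth)
  expect_lt(max(errs), 0.5)
})

test_that("corner detection is equivariant under sub-pixel translation", {
  delta <- c(3.2, -1.7)
  base <- quiet_truth("water")
  moved <- quiet_truth("water",
                       distortion = make_distortion(translation = delta))
  cs0 <- locate_corners(binarize_frame(denoise_frame(generate_frame(base), 1)),
                        generate_frame(base))
  cs1 <- locate_corners(binarize_frame(denoise_frame(generate_frame(moved), 1)),
                        generate_frame(moved))
  shift <- cs1$corners - cs0$corners
  expect_lt(max(abs(sweep(shift, 2, delta))), 0.2)
})

test_that("corner refinement agrees with a brute-force centroid oracle", {
  for (preset in c("water", "methanol")) {
    truth <- quiet_truth(preset)
    fr <- generate_frame(truth)
    cs <- locate_corners(binarize_frame(denoise_frame(fr, 1)), fr, 8)
    for (k in 1:4) {
      oracle <- wcog_oracle(fr, true_corners(truth)[k, ], 8)
      expect_lt(sqrt(sum((cs$corners[k, ] - oracle)^2)), 0.25)
    }
  }
})

test_that("degenerate masks produce stage-specific errors", {
  expect_error(
    locate_corners(matrix(FALSE, 10, 10), matrix(0, 10, 10)),
    "no edge pixels found"
  )
  # a single blob gives no resolvable corner structure
  m <- matrix(FALSE, 50, 50)
  m[24:26, 24:26] <- TRUE
  expect_error(locate_corners(m, matrix(1, 50, 50)))
})

test_that("four-point homography reproduces exact correspondences", {
  can <- square_corners(c(480L, 480L), 60)
  # identity
  tr <- compute_transform(can, can)
  expect_equal(tr$matrix, diag(3), tolerance = 1e-9)
  # pure translation
  det <- can + matrix(c(5, 5), 4, 2, byrow = TRUE)
  tr <- compute_transform(det, can)
  expect_equal(transform_points(tr, det), can, tolerance = 1e-9)
  expect_equal(tr$matrix[1:2, 3], c(-5, -5), tolerance = 1e-9)
  # synthesize-and-solve round trip through a random invertible affine
  set.seed(11)
  for (i in 1:10) {
    A <- diag(2) + matrix(rnorm(4, 0, 0.05), 2, 2)
    b <- rnorm(2, 0, 10)
    det <- t(A %*% t(can) + b)
    for (method in c("homography", "affine")) {
      tr <- compute_transform(det, can, method = method)
      expect_lt(max(abs(transform_points(tr, det) - can)), 1e-6)
    }
  }
})

test_that("collinear corner sets are rejected", {
  bad <- rbind(c(1, 1), c(1, 2), c(1, 3), c(2, 1))
  can <- square_corners()
  expect_error(compute_transform(bad, can), "convex")
})

test_that("warping is exact for identity and integer translations", {
  set.seed(3)
  fr <- matrix(runif(400), 20, 20)
  can <- rbind(c(2, 2), c(2, 19), c(19, 19), c(19, 2))
  tr_id <- compute_transform(can, can)
  expect_identical(warp_frame(fr, tr_id), fr)
  # impulse moved by an integer translation keeps its value
  imp <- matrix(0, 20, 20)
  imp[8, 5] <- 42
  tr <- compute_transform(can, can + matrix(c(3, 2), 4, 2, byrow = TRUE))
  w <- warp_frame(imp, tr)
  expect_equal(w[11, 7], 42)
  expect_equal(sum(w != 0), 1)
})

test_that("a drifted fixture registers back onto the canonical square", {
  set.seed(21)
  cfg <- pipeline_config()
  can <- config_canonical_corners(cfg)
  truth <- vipa_preset("water", snr = 20, seed = 21,
                       distortion = random_drift(5, 0.02, centre = c(240, 240)))
  fr <- generate_frame(truth)
  res <- process_frame(fr, cfg)
  cs2 <- locate_corners(
    binarize_frame(denoise_frame(res$warped, cfg$denoise_sigma),
                   cfg$binarize_fraction),
    res$warped, cfg$refine_halfwidth
  )
  expect_lt(max(sqrt(rowSums((cs2$corners - can)^2))), 0.5)
})

test_that("re-warping an already canonical frame moves no corner by 0.1 px", {
  cfg <- pipeline_config()
  can <- config_canonical_corners(cfg)
  truth <- quiet_truth("water")  # nominal geometry == canonical geometry
  fr <- generate_frame(truth)
  cs <- locate_corners(binarize_frame(denoise_frame(fr, 1)), fr)
  w <- warp_frame(fr, compute_transform(cs, can))
  cs2 <- locate_corners(binarize_frame(denoise_frame(w, 1)), w)
  expect_lt(max(sqrt(rowSums((cs2$corners - cs$corners)^2))), 0.1)
})
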