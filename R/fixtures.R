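# Synthetic VIPA frame generator.
#
# A dual-stage VIPA spectrometer disperses the spectrum onto a square pattern:
# elastically scattered (Rayleigh) light saturates the detector at the four
# corners and along the horizontal/vertical blooming streaks through them,
# while the Stokes and anti-Stokes Brillouin doublet sits on the main
# diagonal. The generator renders that pattern analytically with full ground
# truth so every downstream stage can be validated without instrument data.
#
# Coordinate convention used throughout the package: (row, col), 1-based,
# pixel centres at integer coordinates, origin at the top-left of the frame.
# Corners are always ordered [top-left, top-right, bottom-right, bottom-left]
# and spectral data lie on the top-left -> bottom-right diagonal.

#' Identity pattern distortion
#'
#' @return A 2x3 affine matrix that leaves the nominal pattern unchanged.
#'   The first two columns act on (row, col), the third is a translation.
#' @export
identity_distortion <- function() {
  cbind(diag(2), c(0, 0))
}

#' Build an affine pattern distortion
#'
#' Composes a small drift of the spectral pattern on the detector: a
#' translation plus optional shear and isotropic scale, as produced by laser
#' drift or slow mechanical instability of the spectrometer.
#'
#' @param translation Numeric length-2, (row, col) shift in pixels.
#' @param shear Numeric length-2, off-diagonal shear coefficients
#'   (dimensionless; 0.02 means 2 percent).
#' @param scale Isotropic scale factor about the frame centre origin.
#' @param centre Numeric length-2 point the linear part pivots about
#'   (defaults to the origin; pass the pattern centre for drift that keeps
#'   the square roughly in place).
#' @return A 2x3 affine matrix suitable for the `distortion` field of
#'   [fixture_truth()].
#' @export
make_distortion <- function(translation = c(0, 0), shear = c(0, 0),
                            scale = 1, centre = c(0, 0)) {
  A <- matrix(c(scale, shear[2], shear[1], scale), 2, 2)
  t <- translation + centre - A %*% centre
  cbind(A, as.numeric(t))
}

#' Draw a random small drift distortion
#'
#' Uses the current RNG state. Translation components are uniform in
#' `[-max_translation, max_translation]` pixels and shear components uniform
#' in `[-max_shear, max_shear]`.
#'
#' @param max_translation Maximum absolute translation per axis, px.
#' @param max_shear Maximum absolute shear coefficient.
#' @param centre Pivot point for the shear (pattern centre recommended).
#' @return A 2x3 affine distortion matrix.
#' @export
random_drift <- function(max_translation = 5, max_shear = 0.02,
                         centre = c(0, 0)) {
  make_distortion(
    translation = stats::runif(2, -max_translation, max_translation),
    shear = stats::runif(2, -max_shear, max_shear),
    centre = centre
  )
}

#' Apply a 2x3 affine distortion to points
#'
#' @param points An n x 2 matrix of (row, col) positions.
#' @param distortion A 2x3 affine matrix.
#' @return The mapped n x 2 matrix.
#' @export
apply_distortion <- function(points, distortion) {
  points <- rbind(points)  # tolerate a bare length-2 vector
  out <- points %*% t(distortion[, 1:2]) +
    matrix(distortion[, 3], nrow(points), 2, byrow = TRUE)
  dimnames(out) <- dimnames(points)
  out
}

#' Nominal corner positions of the dispersion square
#'
#' @param frame_shape Integer length-2, (rows, cols) of the frame.
#' @param margin Distance in px from the frame border to the square.
#' @return A 4x2 matrix of (row, col) corner positions ordered
#'   top-left, top-right, bottom-right, bottom-left.
#' @export
square_corners <- function(frame_shape = c(480L, 480L), margin = 60) {
  lo <- margin + 1
  hr <- frame_shape[1] - margin
  hc <- frame_shape[2] - margin
  m <- rbind(
    tl = c(lo, lo),
    tr = c(lo, hc),
    br = c(hr, hc),
    bl = c(hr, lo)
  )
  colnames(m) <- c("row", "col")
  m
}

#' Ground truth for one synthetic VIPA frame
#'
#' Collects the geometry, spectroscopy and detector parameters that fully
#' determine a synthetic frame. Spectral positions follow the free spectral
#' range (FSR) calibration: a Brillouin shift `nu` sits at arc-length fraction
#' `nu / fsr` along the corner-to-corner diagonal (Stokes side) and at
#' `1 - nu / fsr` (anti-Stokes side).
#'
#' Detector-count defaults (background, amplitudes, saturation) are package
#' assumptions chosen to resemble a 16-bit sCMOS exposure in which Rayleigh
#' light saturates while the Brillouin doublet stays far below clip level;
#' they are documented in the methods vignette.
#'
#' @param frame_shape Integer (rows, cols) of the detector frame.
#' @param margin Border margin of the nominal dispersion square, px.
#' @param fsr Free spectral range of the spectrometer, GHz.
#' @param brillouin_shift Brillouin frequency shift, GHz; must lie in
#'   `(0, fsr / 2)`.
#' @param brillouin_fwhm Brillouin linewidth (FWHM), GHz.
#' @param rayleigh_amplitude Un-clipped peak amplitude of the Rayleigh spots,
#'   counts. Values above `saturation_level` produce the realistic clipped
#'   plateau.
#' @param brillouin_amplitude Peak amplitude of each Brillouin peak, counts.
#' @param background_level Constant detector background, counts.
#' @param noise_sigma Standard deviation of additive Gaussian noise, counts.
#' @param saturation_level Detector clip level, counts.
#' @param distortion 2x3 affine matrix applied to the nominal pattern
#'   geometry (drift emulation).
#' @param seed Integer RNG seed; identical truth implies a bit-identical
#'   frame.
#' @param spot_sigma Gaussian width of the Rayleigh spots, px.
#' @param streak_sigma Gaussian cross-section width of the saturation
#'   streaks, px.
#' @param streak_gain Streak amplitude in units of `saturation_level`;
#'   values > 1 give the flat-topped, fully saturated streaks seen on real
#'   detectors.
#' @param band_sigma Gaussian cross-section width of the Brillouin ridge
#'   perpendicular to the dispersion diagonal, px.
#' @return An object of class `fixture_truth`.
#' @seealso [vipa_preset()], [generate_frame()], [true_corners()]
#' @export
fixture_truth <- function(frame_shape = c(480L, 480L),
                          margin = 60,
                          fsr = 30,
                          brillouin_shift = 7.5,
                          brillouin_fwhm = 0.65,
                          rayleigh_amplitude = 2e5,
                          brillouin_amplitude = 800,
                          background_level = 100,
                          noise_sigma = 40,
                          saturation_level = 65535,
                          distortion = identity_distortion(),
                          seed = 1L,
                          spot_sigma = 2,
                          streak_sigma = 1.5,
                          streak_gain = 2.5,
                          band_sigma = 1.5) {
  truth <- structure(
    list(
      frame_shape = as.integer(frame_shape),
      corners = square_corners(frame_shape, margin),
      fsr = fsr,
      brillouin_shift = brillouin_shift,
      brillouin_fwhm = brillouin_fwhm,
      rayleigh_amplitude = rayleigh_amplitude,
      brillouin_amplitude = brillouin_amplitude,
      background_level = background_level,
      noise_sigma = noise_sigma,
      saturation_level = saturation_level,
      distortion = distortion,
      seed = as.integer(seed),
      spot_sigma = spot_sigma,
      streak_sigma = streak_sigma,
      streak_gain = streak_gain,
      band_sigma = band_sigma
    ),
    class = "fixture_truth"
  )
  validate_truth(truth)
  truth
}

validate_truth <- function(truth) {
  with(truth, {
    if (!(brillouin_shift > 0 && brillouin_shift < fsr / 2)) {
      stop("brillouin_shift must lie strictly between 0 and fsr/2 (",
           fsr / 2, " GHz)", call. = FALSE)
    }
    if (brillouin_fwhm <= 0) stop("brillouin_fwhm must be > 0", call. = FALSE)
    if (noise_sigma < 0) stop("noise_sigma must be >= 0", call. = FALSE)
    if (!is.matrix(distortion) || !all(dim(distortion) == c(2, 3))) {
      stop("distortion must be a 2x3 affine matrix", call. = FALSE)
    }
    if (abs(det(distortion[, 1:2])) < 1e-12) {
      stop("distortion matrix is singular", call. = FALSE)
    }
  })
  tc <- true_corners(truth)
  inside <- tc[, 1] > 1 & tc[, 1] < truth$frame_shape[1] &
    tc[, 2] > 1 & tc[, 2] < truth$frame_shape[2]
  if (!all(inside)) {
    stop("distorted corners fall outside the frame", call. = FALSE)
  }
  invisible(truth)
}

#' Corner positions after drift
#'
#' @param truth A [fixture_truth()] object.
#' @return The 4x2 matrix of distorted (row, col) corner positions — the
#'   positions a registration stage should recover.
#' @export
true_corners <- function(truth) {
  apply_distortion(truth$corners, truth$distortion)
}

#' Ground-truth Brillouin peak positions along the dispersion diagonal
#'
#' Positions are expressed as arc length (px) from the top-left corner along
#' the top-left -> bottom-right diagonal; applying the FSR calibration to
#' them returns `brillouin_shift` exactly.
#'
#' @param truth A [fixture_truth()] object.
#' @return Named numeric: `stokes` and `antistokes` arc positions, plus the
#'   diagonal length as attribute `diagonal_px`.
#' @export
true_peak_positions <- function(truth) {
  tc <- true_corners(truth)
  d <- sqrt(sum((tc["br", ] - tc["tl", ])^2))
  f <- truth$brillouin_shift / truth$fsr
  structure(c(stokes = f * d, antistokes = (1 - f) * d), diagonal_px = d)
}

#' Material presets for the synthetic generator
#'
#' Shift/linewidth pairs follow literature reference values for the two
#' calibration liquids commonly used to validate Brillouin spectrometers:
#' methanol (5.6 GHz shift, 0.7 GHz linewidth) and water (7.5 GHz, 0.65 GHz)
#' at 532 nm. The `"gel"` preset emulates a collagen gelatin hydrogel, whose
#' shift falls between water and dense protein; its default of 8 GHz (and any
#' value in roughly 7-9 GHz) can be overridden via `shift`.
#'
#' @param name One of `"methanol"`, `"water"`, `"gel"`.
#' @param snr Peak signal-to-noise ratio, defined as
#'   `brillouin_amplitude / noise_sigma`. Use `Inf` for noiseless frames.
#' @param shift Optional override of the preset shift in GHz (mainly for the
#'   gel preset).
#' @param ... Further arguments passed to [fixture_truth()] (for example
#'   `seed` or `distortion`).
#' @return A [fixture_truth()] object.
#' @examples
#' truth <- vipa_preset("water", snr = Inf)
#' truth$brillouin_shift
#' @export
vipa_preset <- function(name, snr = 20, shift = NULL, ...) {
  presets <- list(
    methanol = list(shift = 5.6, fwhm = 0.7),
    water    = list(shift = 7.5, fwhm = 0.65),
    gel      = list(shift = 8.0, fwhm = 1.0)
  )
  if (length(name) != 1 || !name %in% names(presets)) {
    stop("unknown preset ", deparse(name), "; available presets: ",
         paste(names(presets), collapse = ", "), call. = FALSE)
  }
  p <- presets[[name]]
  if (!is.null(shift)) p$shift <- shift
  args <- list(...)
  args$brillouin_shift <- p$shift
  args$brillouin_fwhm <- p$fwhm
  truth <- do.call(fixture_truth, args)
  truth$noise_sigma <- if (is.finite(snr)) truth$brillouin_amplitude / snr else 0
  validate_truth(truth)
  truth
}

# Perpendicular distance from every pixel to the infinite line through p, q.
.line_distance <- function(rr, cc, p, q) {
  d <- q - p
  len <- sqrt(sum(d^2))
  abs(d[1] * (cc - p[2]) - d[2] * (rr - p[1])) / len
}

#' Render a synthetic VIPA frame
#'
#' Draws the four Rayleigh spots (2-D Gaussians clipped at the saturation
#' level), fully saturated horizontal/vertical blooming streaks through each
#' corner pair, and the Stokes/anti-Stokes Brillouin doublet as Lorentzian
#' ridges along the top-left -> bottom-right diagonal at arc positions
#' consistent with the FSR calibration. The drift distortion acts on the
#' pattern geometry (corners, streak lines, diagonal) so that sub-pixel
#' ground truth stays exact; clipping is applied before additive Gaussian
#' noise. Identical truth (including seed) yields a bit-identical frame.
#'
#' @param truth A [fixture_truth()] object.
#' @return A numeric rows x cols matrix of detector counts.
#' @export
generate_frame <- function(truth) {
  stopifnot(inherits(truth, "fixture_truth"))
  validate_truth(truth)
  nr <- truth$frame_shape[1]
  nc <- truth$frame_shape[2]
  rr <- matrix(seq_len(nr), nr, nc)
  cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  img <- matrix(truth$background_level, nr, nc)

  P <- true_corners(truth)

  # Saturation streaks: the blooming lines through each pair of corners.
  streak_amp <- truth$streak_gain * truth$saturation_level
  pairs <- list(c("tl", "tr"), c("bl", "br"), c("tl", "bl"), c("tr", "br"))
  for (pq in pairs) {
    d <- .line_distance(rr, cc, P[pq[1], ], P[pq[2], ])
    img <- img + streak_amp * exp(-d^2 / (2 * truth$streak_sigma^2))
  }

  # Rayleigh corner spots.
  for (k in seq_len(4)) {
    d2 <- (rr - P[k, 1])^2 + (cc - P[k, 2])^2
    img <- img + truth$rayleigh_amplitude * exp(-d2 / (2 * truth$spot_sigma^2))
  }

  # Brillouin doublet: Lorentzian along the diagonal arc length, Gaussian
  # cross-section perpendicular to it.
  p0 <- P["tl", ]
  p1 <- P["br", ]
  diag_len <- sqrt(sum((p1 - p0)^2))
  u <- (p1 - p0) / diag_len
  v <- c(-u[2], u[1])
  t_arc <- (rr - p0[1]) * u[1] + (cc - p0[2]) * u[2]
  d_perp <- (rr - p0[1]) * v[1] + (cc - p0[2]) * v[2]
  gam_px <- truth$brillouin_fwhm / truth$fsr * diag_len
  cross <- exp(-d_perp^2 / (2 * truth$band_sigma^2))
  for (centre in unname(true_peak_positions(truth))) {
    img <- img + truth$brillouin_amplitude * cross *
      (gam_px / 2)^2 / ((t_arc - centre)^2 + (gam_px / 2)^2)
  }

  img <- pmin(img, truth$saturation_level)

  if (truth$noise_sigma > 0) {
    withr::with_seed(truth$seed, {
      img <- img + matrix(stats::rnorm(nr * nc, 0, truth$noise_sigma), nr, nc)
    })
  }
  img
}
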