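# Line-shape fitting.
#
# Brillouin peaks are fitted with FWHM-parameterized Lorentzian (and, for
# comparison, Gaussian) profiles by nonlinear least squares; "linewidth"
# throughout the package means the full width at half maximum in GHz. Fit
# quality is reported as RMS = sqrt(mean squared residual) and
# R^2 = 1 - SS_res / SS_tot. No deconvolution of the instrumental function
# is applied: fitted widths are apparent widths.

#' Lorentzian line shape
#'
#' `A * (fwhm/2)^2 / ((nu - centre)^2 + (fwhm/2)^2) + offset`; apex value
#' `A + offset` at `nu = centre`, half maximum above offset at
#' `centre +/- fwhm / 2`.
#'
#' @param nu Frequency, GHz (vectorized).
#' @param amplitude Peak amplitude above offset, counts.
#' @param centre Peak centre, GHz.
#' @param fwhm Full width at half maximum, GHz (> 0).
#' @param offset Constant baseline, counts.
#' @return Model intensity, counts.
#' @export
lorentzian <- function(nu, amplitude, centre, fwhm, offset = 0) {
  hw2 <- (fwhm / 2)^2
  amplitude * hw2 / ((nu - centre)^2 + hw2) + offset
}

#' Gaussian line shape (FWHM parameterization)
#'
#' `A * exp(-4 ln 2 (nu - centre)^2 / fwhm^2) + offset`; same apex and
#' half-maximum conventions as [lorentzian()].
#'
#' @inheritParams lorentzian
#' @return Model intensity, counts.
#' @export
gaussian_peak <- function(nu, amplitude, centre, fwhm, offset = 0) {
  amplitude * exp(-4 * log(2) * (nu - centre)^2 / fwhm^2) + offset
}

# Moment-based starting values shared by both models.
.init_peak <- function(x, y) {
  n <- length(y)
  offset <- mean(y[c(1, n)])
  i_max <- which.max(y)
  amplitude <- max(y[i_max] - offset, .Machine$double.eps)
  centre <- x[i_max]
  half <- offset + amplitude / 2
  # half-maximum crossings by linear interpolation, each side of the apex
  xl <- NA_real_
  if (i_max > 1) {
    below <- which(y[1:(i_max - 1)] <= half)
    if (length(below)) {
      i <- max(below)
      xl <- x[i] + (half - y[i]) / (y[i + 1] - y[i]) * (x[i + 1] - x[i])
    }
  }
  xr <- NA_real_
  if (i_max < n) {
    below <- which(y[(i_max + 1):n] <= half) + i_max
    if (length(below)) {
      i <- min(below)
      xr <- x[i - 1] + (half - y[i - 1]) / (y[i] - y[i - 1]) * (x[i] - x[i - 1])
    }
  }
  fwhm <- if (!is.na(xl) && !is.na(xr)) {
    xr - xl
  } else if (!is.na(xl)) {
    2 * (centre - xl)
  } else if (!is.na(xr)) {
    2 * (xr - centre)
  } else {
    diff(range(x)) / 2
  }
  list(amplitude = amplitude, centre = centre,
       fwhm = max(fwhm, .Machine$double.eps), offset = offset)
}

#' Fit a line shape to one peak segment
#'
#' Nonlinear least squares (Levenberg-Marquardt) from moment-based starting
#' values: centre at the apex frequency, amplitude as apex minus baseline,
#' width from the half-maximum crossings, offset from the segment edges.
#' The optimizer is bounded to `amplitude > 0`, centre inside the segment,
#' and `0 < fwhm <= fsr / 2` (when the spectrum carries an FSR), preventing
#' sign flips to negative peaks.
#'
#' @param spectrum A `calibrated_spectrum` (see [calibrate_spectrum()]).
#' @param segment One row of the data.frame returned by [segment_peaks()]
#'   (or any list with `start` and `end` channel values).
#' @param kind `"lorentzian"` or `"gaussian"`.
#' @param max_iter Iteration budget for the optimizer.
#' @param tol Relative convergence tolerance.
#' @return An object of class `peak_fit`: list with `kind`, `parameters`
#'   (amplitude, centre, fwhm, offset), `shift` and `fwhm` in GHz, `rms`,
#'   `r_squared`, `n_channels`, `converged`, `side`, and the fitted data
#'   (`nu`, `intensity`, `fitted`).
#' @export
fit_peak <- function(spectrum, segment,
                     kind = c("lorentzian", "gaussian"),
                     max_iter = 200, tol = 1e-8) {
  kind <- match.arg(kind)
  stopifnot(inherits(spectrum, "calibrated_spectrum"))
  sel <- spectrum$channels >= segment$start & spectrum$channels <= segment$end
  x <- spectrum$frequencies[sel]
  y <- spectrum$intensities[sel]
  # on the folded axis the anti-Stokes side runs high-to-low in frequency;
  # sort ascending so the width initializer sees a conventional axis
  ord <- order(x)
  x <- x[ord]
  y <- y[ord]
  if (length(y) < 5) {
    stop("segment too short to fit: ", length(y),
         " channels (need >= 5 for a 4-parameter model)", call. = FALSE)
  }
  init <- .init_peak(x, y)
  fsr <- spectrum$fsr
  upper_fwhm <- if (!is.null(fsr)) fsr / 2 else Inf
  model_fun <- if (kind == "lorentzian") lorentzian else gaussian_peak

  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ model_fun(x, amplitude, centre, fwhm, offset),
      start = init,
      lower = c(amplitude = 1e-12, centre = min(x), fwhm = 1e-9,
                offset = -Inf),
      upper = c(amplitude = Inf, centre = max(x), fwhm = upper_fwhm,
                offset = Inf),
      control = minpack.lm::nls.lm.control(maxiter = max_iter, ftol = tol,
                                           ptol = tol)
    ),
    error = function(e) NULL
  )

  if (is.null(fit)) {
    pars <- unlist(init)
    converged <- FALSE
  } else {
    pars <- stats::coef(fit)
    converged <- isTRUE(fit$convInfo$isConv) ||
      # nls.lm "info" codes 1:3 indicate a satisfied convergence test
      isTRUE(fit$convInfo$stopCode %in% 1:3)
  }
  fitted_y <- model_fun(x, pars["amplitude"], pars["centre"], pars["fwhm"],
                        pars["offset"])
  resid <- y - fitted_y
  ss_res <- sum(resid^2)
  ss_tot <- sum((y - mean(y))^2)
  structure(
    list(
      kind = kind,
      parameters = pars,
      shift = unname(pars["centre"]),
      fwhm = unname(pars["fwhm"]),
      rms = sqrt(mean(resid^2)),
      r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_,
      n_channels = length(y),
      converged = converged,
      side = if (!is.null(segment$side)) segment$side else NA_character_,
      nu = x,
      intensity = y,
      fitted = fitted_y
    ),
    class = "peak_fit"
  )
}

#' Combine Stokes and anti-Stokes fits
#'
#' The combined shift and linewidth are the arithmetic means of the two
#' sides; their absolute difference is reported as a quality-control
#' asymmetry metric. If one side failed to converge, the converged side is
#' used alone and a QC flag records the fallback.
#'
#' @param stokes,antistokes `peak_fit` results for the two sides; either may
#'   be `NULL` if no segment was found on that side.
#' @return A list with `shift`, `fwhm` (GHz), `asymmetry_shift`,
#'   `asymmetry_fwhm`, `r_squared` and `rms` (means over the sides used),
#'   and `qc_flags` (character vector, empty when both sides converged).
#' @export
combine_sides <- function(stokes, antistokes) {
  usable <- function(f) !is.null(f) && isTRUE(f$converged)
  flags <- character()
  if (!usable(stokes)) {
    flags <- c(flags, if (is.null(stokes)) "stokes_missing"
               else "stokes_unconverged")
  }
  if (!usable(antistokes)) {
    flags <- c(flags, if (is.null(antistokes)) "antistokes_missing"
               else "antistokes_unconverged")
  }
  sides <- Filter(usable, list(stokes = stokes, antistokes = antistokes))
  if (length(sides) == 0) {
    return(list(shift = NA_real_, fwhm = NA_real_,
                asymmetry_shift = NA_real_, asymmetry_fwhm = NA_real_,
                r_squared = NA_real_, rms = NA_real_,
                qc_flags = c(flags, "no_converged_side")))
  }
  shifts <- vapply(sides, function(f) f$shift, numeric(1))
  widths <- vapply(sides, function(f) f$fwhm, numeric(1))
  list(
    shift = mean(shifts),
    fwhm = mean(widths),
    asymmetry_shift = if (length(shifts) == 2) abs(shifts[[1]] - shifts[[2]])
                      else NA_real_,
    asymmetry_fwhm = if (length(widths) == 2) abs(widths[[1]] - widths[[2]])
                     else NA_real_,
    r_squared = mean(vapply(sides, function(f) f$r_squared, numeric(1))),
    rms = mean(vapply(sides, function(f) f$rms, numeric(1))),
    qc_flags = flags
  )
}
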