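# Per-frame orchestration and hyperspectral map assembly.

#' Pipeline configuration
#'
#' Collects every tunable of the per-frame analysis chain. Defaults follow
#' the package's canonical geometry (480 px frames, 360 px square) and the
#' processing conventions described in the methods vignette.
#'
#' @param fsr Free spectral range, GHz.
#' @param canonical_side Side length of the canonical square, px. The
#'   default matches the generator's nominal geometry: a 480 px frame with
#'   60 px margins puts corners at rows/cols 61 and 420, i.e. a side of
#'   359 px between pixel centres.
#' @param canonical_margin Margin between canonical square and frame
#'   border, px.
#' @param denoise_sigma Gaussian denoise width before thresholding, px.
#' @param binarize_fraction Threshold as fraction of the frame maximum.
#' @param refine_halfwidth Corner-refinement window half-width, px.
#' @param band_halfwidth Spectral band half-width, px.
#' @param segment_window Local-average window half-width, channels.
#' @param segment_exclusion Channels masked at each Rayleigh skirt. The
#'   default `NULL` resolves to `band_halfwidth + 5`: a band of half-width
#'   `h` geometrically intersects the saturated Rayleigh streaks within `h`
#'   channels of either end, so the exclusion zone must always cover at
#'   least that much.
#' @param segment_k Threshold multiplier on the local mean.
#' @param fit_pad Channels added to each side of a detected segment before
#'   line-shape fitting (clipped at the Rayleigh exclusion zone and at the
#'   axis midpoint where the frequency axis folds). The local-mean
#'   segmentation isolates the peak core; including some baseline wings
#'   stabilizes the width and offset estimates.
#' @param fit_kind `"lorentzian"` (default) or `"gaussian"`.
#' @param transform_method `"homography"` or `"affine"`.
#' @param alpha Display contrast constant (display only; never affects the
#'   quantitative chain).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(fsr = 30,
                            canonical_side = 359,
                            canonical_margin = 60,
                            denoise_sigma = 1,
                            binarize_fraction = 0.95,
                            refine_halfwidth = 8,
                            band_halfwidth = 10,
                            segment_window = 10,
                            segment_exclusion = NULL,
                            segment_k = 1,
                            fit_pad = 15,
                            fit_kind = "lorentzian",
                            transform_method = "homography",
                            alpha = 0.5) {
  cfg <- as.list(environment())
  if (is.null(cfg$segment_exclusion)) {
    cfg$segment_exclusion <- cfg$band_halfwidth + 5
  }
  stopifnot(
    cfg$fsr > 0, cfg$canonical_side > 0, cfg$canonical_margin >= 0,
    cfg$denoise_sigma >= 0,
    cfg$binarize_fraction > 0, cfg$binarize_fraction < 1,
    cfg$refine_halfwidth > 0, cfg$band_halfwidth > 0,
    cfg$segment_window >= 1, cfg$segment_exclusion >= 0, cfg$segment_k > 0,
    cfg$fit_pad >= 0,
    cfg$alpha > 0, cfg$alpha <= 1
  )
  cfg$fit_kind <- match.arg(cfg$fit_kind, c("lorentzian", "gaussian"))
  cfg$transform_method <- match.arg(cfg$transform_method,
                                    c("homography", "affine"))
  structure(cfg, class = "pipeline_config")
}

#' Canonical corner positions for a configuration
#'
#' @param config A [pipeline_config()].
#' @return 4x2 matrix of canonical (row, col) corners (tl, tr, br, bl).
#' @export
config_canonical_corners <- function(config) {
  side <- config$canonical_side
  m <- config$canonical_margin
  out <- rbind(
    tl = c(m + 1, m + 1),
    tr = c(m + 1, m + 1 + side),
    br = c(m + 1 + side, m + 1 + side),
    bl = c(m + 1 + side, m + 1)
  )
  colnames(out) <- c("row", "col")
  out
}

# Run one stage, rethrowing any error with the stage name attached so a
# frame-level failure reports where the chain broke.
.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(structure(
      class = c("vipa_stage_error", "error", "condition"),
      list(message = paste0("stage '", name, "': ", conditionMessage(e)),
           call = NULL, stage = name)
    ))
  })
}

#' Process one frame through the full analysis chain
#'
#' Runs denoise, binarize, corner localization, homography, warp, band
#' extraction, maximum projection, frequency calibration, peak segmentation
#' and line-shape fitting of both sides, then combines Stokes and
#' anti-Stokes into one shift/linewidth estimate. Every intermediate is
#' returned for quality control. Errors carry the name of the failed stage.
#'
#' @param frame Numeric matrix of detector counts.
#' @param config A [pipeline_config()].
#' @return A list of class `frame_result`: `corners`, `transform`, `warped`,
#'   `band`, `spectrum` (calibrated), `segments`, `fits` (per side),
#'   `combined` (shift, fwhm, QC), `drift` (detected vs canonical corner
#'   offset, px).
#' @export
process_frame <- function(frame, config = pipeline_config()) {
  stopifnot(is.matrix(frame), inherits(config, "pipeline_config"))
  canonical <- config_canonical_corners(config)
  out_shape <- c(config$canonical_side + 2 * config$canonical_margin + 1,
                 config$canonical_side + 2 * config$canonical_margin + 1)

  den <- .stage("denoise", denoise_frame(frame, config$denoise_sigma))
  mask <- .stage("binarize", binarize_frame(den, config$binarize_fraction))
  corners <- .stage("locate_corners",
                    locate_corners(mask, frame, config$refine_halfwidth))
  transform <- .stage("compute_transform",
                      compute_transform(corners, canonical,
                                        method = config$transform_method))
  warped <- .stage("warp", warp_frame(frame, transform, out_shape))
  band <- .stage("extract_band",
                 extract_band(warped, canonical, config$band_halfwidth,
                              frame = frame, transform = transform))
  spectrum <- .stage("project_max", project_max(band))
  spectrum <- .stage("calibrate", calibrate_spectrum(spectrum, config$fsr))
  segments <- .stage("segment_peaks",
                     segment_peaks(spectrum, config$segment_window,
                                   config$segment_exclusion,
                                   config$segment_k))
  if (nrow(segments) == 0) {
    .stage("segment_peaks", stop("no peak segments found", call. = FALSE))
  }

  pick_side <- function(side) {
    s <- segments[segments$side == side, , drop = FALSE]
    if (nrow(s) == 0) return(NULL)
    s[which.max(s$apex_intensity), , drop = FALSE]
  }
  mid <- (spectrum$r0 + spectrum$r1) / 2
  pad_segment <- function(seg) {
    lo <- ceiling(spectrum$r0 + config$segment_exclusion)
    hi <- floor(spectrum$r1 - config$segment_exclusion)
    if (seg$side == "stokes") hi <- min(hi, floor(mid))
    if (seg$side == "antistokes") lo <- max(lo, ceiling(mid))
    seg$start <- max(seg$start - config$fit_pad, lo)
    seg$end <- min(seg$end + config$fit_pad, hi)
    seg
  }
  fit_side <- function(seg) {
    if (is.null(seg) || seg$n_channels < 5) return(NULL)
    .stage("fit_peak",
           fit_peak(spectrum, pad_segment(seg), kind = config$fit_kind))
  }
  fits <- list(stokes = fit_side(pick_side("stokes")),
               antistokes = fit_side(pick_side("antistokes")))
  combined <- .stage("combine_sides",
                     combine_sides(fits$stokes, fits$antistokes))

  structure(
    list(
      corners = corners,
      transform = transform,
      warped = warped,
      band = band,
      spectrum = spectrum,
      segments = segments,
      fits = fits,
      combined = combined,
      drift = corners$corners - canonical
    ),
    class = "frame_result"
  )
}

#' Process many frames against stage positions into a map
#'
#' Frame-level failures are caught and recorded as missing map positions
#' with the failed stage name; a long scan survives isolated bad frames.
#'
#' @param frames List of frame matrices (or paths to 16-bit TIFF files,
#'   read via [read_frame()]).
#' @param positions data.frame with `x_um`, `y_um` stage coordinates, one
#'   row per frame.
#' @param config A [pipeline_config()].
#' @return A `brillouin_map` data.frame, see [assemble_map()].
#' @export
process_frames <- function(frames, positions, config = pipeline_config()) {
  stopifnot(length(frames) == nrow(positions))
  results <- lapply(frames, function(f) {
    if (is.character(f)) f <- read_frame(f)
    tryCatch(process_frame(f, config), error = function(e) e)
  })
  assemble_map(results, positions)
}

#' Assemble per-frame results into a hyperspectral map
#'
#' @param results List of `frame_result` objects (or caught error
#'   conditions for failed frames).
#' @param positions data.frame with `x_um`, `y_um`, one row per result;
#'   duplicated positions are an error.
#' @return A data.frame of class `brillouin_map` with columns `x_um`,
#'   `y_um`, `shift_ghz`, `fwhm_ghz`, `r_squared`, `rms`, `qc_flags`
#'   (semicolon-separated), `ok`, `failure` (failed stage message or `NA`).
#'   Attribute `grid_dim` holds the (n distinct y, n distinct x) scan-grid
#'   size.
#' @export
assemble_map <- function(results, positions) {
  stopifnot(is.data.frame(positions),
            all(c("x_um", "y_um") %in% names(positions)),
            length(results) == nrow(positions))
  if (anyDuplicated(positions[, c("x_um", "y_um")])) {
    stop("duplicated stage positions in the manifest", call. = FALSE)
  }
  rows <- Map(function(res, i) {
    if (inherits(res, "condition")) {
      data.frame(
        x_um = positions$x_um[i], y_um = positions$y_um[i],
        shift_ghz = NA_real_, fwhm_ghz = NA_real_,
        r_squared = NA_real_, rms = NA_real_,
        qc_flags = "", ok = FALSE, failure = conditionMessage(res)
      )
    } else {
      cb <- res$combined
      data.frame(
        x_um = positions$x_um[i], y_um = positions$y_um[i],
        shift_ghz = cb$shift, fwhm_ghz = cb$fwhm,
        r_squared = cb$r_squared, rms = cb$rms,
        qc_flags = paste(cb$qc_flags, collapse = ";"),
        ok = TRUE, failure = NA_character_
      )
    }
  }, results, seq_along(results))
  map <- do.call(rbind, rows)
  attr(map, "grid_dim") <- c(length(unique(map$y_um)),
                             length(unique(map$x_um)))
  class(map) <- c("brillouin_map", class(map))
  map
}

#' Longitudinal modulus from a Brillouin shift
#'
#' Standard backscattering relation (a literature formula, not specific to
#' any one instrument): the acoustic velocity is `v = lambda * nu / (2 n)`
#' and the longitudinal modulus `M = rho * v^2`. Refractive index and mass
#' density must be supplied by the user; no material defaults are assumed.
#'
#' @param shift_ghz Brillouin frequency shift, GHz.
#' @param refractive_index Refractive index of the sample (dimensionless).
#' @param mass_density Mass density, kg/m^3.
#' @param wavelength_nm Laser wavelength, nm.
#' @return Longitudinal modulus in GPa.
#' @examples
#' estimate_modulus(7.5, refractive_index = 1.33, mass_density = 998,
#'                  wavelength_nm = 532)
#' @export
estimate_modulus <- function(shift_ghz, refractive_index, mass_density,
                             wavelength_nm = 532) {
  if (any(shift_ghz < 0)) stop("shift_ghz must be >= 0", call. = FALSE)
  if (refractive_index <= 0 || mass_density <= 0 || wavelength_nm <= 0) {
    stop("refractive_index, mass_density and wavelength_nm must be > 0",
         call. = FALSE)
  }
  v <- wavelength_nm * 1e-9 * shift_ghz * 1e9 / (2 * refractive_index)
  mass_density * v^2 / 1e9
}
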