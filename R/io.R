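# File I/O: 16-bit grayscale TIFF frames, JSON ground-truth sidecars,
# CSV spectra, manifests and maps.

#' Read a 16-bit grayscale TIFF frame
#'
#' @param path Path to the TIFF file.
#' @return Numeric matrix of detector counts (0..65535 for 16-bit input).
#' @export
read_frame <- function(path) {
  img <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(img)) == 3) img <- img[, , 1]
  storage.mode(img) <- "double"
  img
}

#' Write a frame as 16-bit grayscale TIFF
#'
#' Counts are clamped to `[0, 65535]` and rounded to integers on write.
#'
#' @param frame Numeric matrix of counts.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_frame <- function(frame, path) {
  scaled <- pmin(pmax(round(frame), 0), 65535) / 65535
  tiff::writeTIFF(scaled, path, bits.per.sample = 16)
  invisible(path)
}

#' Write a ground-truth sidecar as JSON
#'
#' @param truth A [fixture_truth()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  obj <- unclass(truth)
  obj$corners <- unname(apply(obj$corners, 1, as.numeric, simplify = FALSE))
  obj$distortion <- as.numeric(t(obj$distortion))  # row-major 6 coefficients
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a ground-truth sidecar written by [write_truth()]
#'
#' @param path Path to the JSON file.
#' @return A [fixture_truth()] object.
#' @export
read_truth <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  fixture_truth(
    frame_shape = obj$frame_shape,
    margin = obj$corners[[1]][1] - 1,
    fsr = obj$fsr,
    brillouin_shift = obj$brillouin_shift,
    brillouin_fwhm = obj$brillouin_fwhm,
    rayleigh_amplitude = obj$rayleigh_amplitude,
    brillouin_amplitude = obj$brillouin_amplitude,
    background_level = obj$background_level,
    noise_sigma = obj$noise_sigma,
    saturation_level = obj$saturation_level,
    distortion = matrix(obj$distortion, 2, 3, byrow = TRUE),
    seed = obj$seed,
    spot_sigma = obj$spot_sigma,
    streak_sigma = obj$streak_sigma,
    streak_gain = obj$streak_gain,
    band_sigma = obj$band_sigma
  )
}

#' Write a calibrated spectrum as CSV
#'
#' Columns: `channel`, `frequency_ghz`, `intensity`.
#'
#' @param spectrum A `calibrated_spectrum`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spectrum_csv <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "calibrated_spectrum"))
  utils::write.csv(
    data.frame(channel = spectrum$channels,
               frequency_ghz = spectrum$frequencies,
               intensity = spectrum$intensities),
    path, row.names = FALSE
  )
  invisible(path)
}

#' Read a frame manifest
#'
#' @param path CSV with columns `path`, `x_um`, `y_um`.
#' @return data.frame of the manifest.
#' @export
read_manifest <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("path", "x_um", "y_um")
  if (!all(need %in% names(m))) {
    stop("manifest must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  m
}

#' Write a Brillouin map as CSV
#'
#' @param map A `brillouin_map` from [assemble_map()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_map_csv <- function(map, path) {
  utils::write.csv(as.data.frame(map), path, row.names = FALSE)
  invisible(path)
}
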