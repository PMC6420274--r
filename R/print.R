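# Compact console displays for the package's S3 objects.

#' @export
print.fixture_truth <- function(x, ...) {
  cat("<fixture_truth> ", x$frame_shape[1], "x", x$frame_shape[2],
      " frame, FSR ", x$fsr, " GHz\n", sep = "")
  cat(sprintf("  shift %.3g GHz, FWHM %.3g GHz, peak SNR %s\n",
              x$brillouin_shift, x$brillouin_fwhm,
              if (x$noise_sigma > 0) {
                sprintf("%.3g", x$brillouin_amplitude / x$noise_sigma)
              } else "Inf (noiseless)"))
  invisible(x)
}

#' @export
print.corner_set <- function(x, ...) {
  cat("<corner_set> refined Rayleigh corners (row, col):\n")
  print(round(x$corners, 3))
  cat(sprintf("  refinement residual: %.3f px\n", x$refinement_residual))
  invisible(x)
}

#' @export
print.calibrated_spectrum <- function(x, ...) {
  cat("<calibrated_spectrum> ", length(x$channels), " channels, FSR ",
      x$fsr, " GHz, Rayleigh at ", round(x$r0, 2), " / ", round(x$r1, 2),
      " px\n", sep = "")
  invisible(x)
}

#' @export
print.frame_result <- function(x, ...) {
  cb <- x$combined
  cat("<frame_result>\n")
  cat(sprintf("  shift: %.4g GHz   FWHM: %.4g GHz\n", cb$shift, cb$fwhm))
  cat(sprintf("  R^2: %.4f   RMS: %.4g counts\n", cb$r_squared, cb$rms))
  if (length(cb$qc_flags)) {
    cat("  QC flags:", paste(cb$qc_flags, collapse = ", "), "\n")
  }
  cat("  segments:", nrow(x$segments), "  drift (tl, px):",
      sprintf("%.2f/%.2f", x$drift[1, 1], x$drift[1, 2]), "\n")
  invisible(x)
}

#' @export
print.peak_fit <- function(x, ...) {
  cat(sprintf("<peak_fit> %s, %s side: centre %.4g GHz, FWHM %.4g GHz\n",
              x$kind, x$side, x$shift, x$fwhm))
  cat(sprintf("  R^2 %.5f, RMS %.4g over %d channels (%s)\n",
              x$r_squared, x$rms, x$n_channels,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}
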