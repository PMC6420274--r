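# Display-only contrast enhancement. These functions never feed the
# quantitative chain: the pipeline's spectral results are identical whether
# or not a frame is rendered for inspection.

#' Contrast normalization for display
#'
#' Maps raw counts to a perceptual intensity in `[0, 1]` by clamping at
#' `mu +/- alpha * sigma` and ramping linearly in between, where `mu` and
#' `sigma` are the mean and standard deviation of the whole frame:
#' output is 0 below `mu - alpha*sigma`, 1 above `mu + alpha*sigma`, and
#' `(I - mu + alpha*sigma) / (2*alpha*sigma)` otherwise. Low-contrast
#' Brillouin signal becomes visible next to saturated Rayleigh streaks.
#'
#' @param frame Numeric matrix of detector counts.
#' @param alpha Scaling constant in `(0, 1]`; smaller values stretch the
#'   contrast harder.
#' @return A matrix of the same shape with values in `[0, 1]`.
#' @export
contrast_normalize <- function(frame, alpha = 0.5) {
  if (length(frame) == 0) stop("frame is empty", call. = FALSE)
  if (!(alpha > 0 && alpha <= 1)) stop("alpha must be in (0, 1]", call. = FALSE)
  mu <- mean(frame)
  sigma <- stats::sd(as.vector(frame))
  if (!is.finite(sigma) || sigma == 0) {
    stop("constant frame (sd = 0): cannot contrast-normalize; ",
         "this usually indicates an acquisition failure", call. = FALSE)
  }
  out <- (frame - mu + alpha * sigma) / (2 * alpha * sigma)
  pmin(pmax(out, 0), 1)
}

#' Pseudo-colour rendering of a normalized frame
#'
#' Applies a monotone, perceptually uniform colour scale to a `[0, 1]`
#' intensity grid.
#'
#' @param normalized Matrix with values in `[0, 1]`, e.g. from
#'   [contrast_normalize()].
#' @param colormap Palette name understood by [grDevices::hcl.colors()];
#'   the default `"viridis"` is perceptually uniform.
#' @param n_colours Number of quantization levels.
#' @return A rows x cols x 3 numeric array of RGB values in `[0, 1]`.
#' @export
to_pseudocolour <- function(normalized, colormap = "viridis",
                            n_colours = 256L) {
  if (any(normalized < 0 | normalized > 1, na.rm = TRUE)) {
    stop("values outside [0, 1]: run contrast_normalize() first",
         call. = FALSE)
  }
  pal <- grDevices::hcl.colors(n_colours, colormap)
  idx <- pmin(n_colours, 1L + as.integer(floor(normalized * n_colours)))
  rgb <- grDevices::col2rgb(pal[idx]) / 255
  out <- array(0, dim = c(nrow(normalized), ncol(normalized), 3))
  for (ch in 1:3) {
    out[, , ch] <- matrix(rgb[ch, ], nrow(normalized), ncol(normalized))
  }
  out
}
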