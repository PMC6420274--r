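# Rayleigh-peak localization and drift correction.
#
# The four saturated Rayleigh peaks at the corners of the dispersion square
# double as fiducial markers: after denoising and thresholding, the centre
# pixels of the saturated streak lines are fitted per corner with one
# horizontal and one vertical least-squares line, whose intersection —
# refined by an intensity-weighted centre of gravity on the raw frame —
# gives each corner at sub-pixel precision. A four-point homography then
# warps the frame onto a canonical square, removing laser drift and pattern
# distortion.

#' Gaussian denoising
#'
#' @param frame Numeric matrix.
#' @param sigma_px Gaussian standard deviation in px; `0` returns the input
#'   unchanged.
#' @return Smoothed matrix of the same shape.
#' @export
denoise_frame <- function(frame, sigma_px = 1) {
  if (sigma_px < 0) stop("sigma_px must be >= 0", call. = FALSE)
  if (sigma_px == 0) return(frame)
  out <- EBImage::gblur(frame, sigma = sigma_px)
  matrix(as.numeric(out), nrow(frame), ncol(frame))
}

#' Threshold at a fraction of the frame maximum
#'
#' Only saturated structure — the Rayleigh spots and their blooming
#' streaks — survives the default 0.95 fraction; the Brillouin signal is
#' orders of magnitude dimmer.
#'
#' @param frame Numeric matrix (typically denoised).
#' @param fraction Threshold as a fraction of `max(frame)`, in `(0, 1)`.
#' @return Logical matrix, `TRUE` where `frame >= fraction * max(frame)`.
#' @export
binarize_frame <- function(frame, fraction = 0.95) {
  if (!(fraction > 0 && fraction < 1)) {
    stop("fraction must be in (0, 1)", call. = FALSE)
  }
  frame >= fraction * max(frame)
}

# Centres of TRUE runs along each column (edge = "h") or row (edge = "v").
# Returns a data.frame with the run centre position, the fixed coordinate
# and the run length. Runs much longer than typical streak crossings (the
# perpendicular streak seen end-on, or merged corner blobs) are dropped by
# an adaptive length filter.
.run_centres <- function(mask, along = c("col", "row")) {
  along <- match.arg(along)
  n_fixed <- if (along == "col") ncol(mask) else nrow(mask)
  res <- vector("list", n_fixed)
  for (j in seq_len(n_fixed)) {
    v <- if (along == "col") mask[, j] else mask[j, ]
    r <- rle(v)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    keep <- r$values
    if (!any(keep)) next
    res[[j]] <- data.frame(
      centre = (starts[keep] + ends[keep]) / 2,
      fixed = j,
      len = r$lengths[keep]
    )
  }
  out <- do.call(rbind, res)
  if (is.null(out)) out <- data.frame(centre = numeric(), fixed = numeric(),
                                      len = numeric())
  out
}

.filter_runs <- function(runs) {
  if (nrow(runs) == 0) return(runs)
  runs[runs$len <= max(5, 2.5 * stats::median(runs$len)), , drop = FALSE]
}

# Least-squares line y ~ x; errors if degenerate.
.fit_line <- function(x, y, what) {
  if (length(x) < 2) {
    stop("corner localization failed at line fit (", what,
         "): fewer than 2 edge-centre pixels", call. = FALSE)
  }
  if (stats::var(x) == 0) {
    stop("corner localization failed at line fit (", what,
         "): edge-centre pixels are collinear along one axis", call. = FALSE)
  }
  stats::coef(stats::lm.fit(cbind(1, x), y))
}

#' Locate the four Rayleigh peaks at sub-pixel precision
#'
#' Implements the corner-finding chain: centre pixels of the thresholded
#' streak lines are computed per column (horizontal edges) and per row
#' (vertical edges); the centre of gravity of the mask assigns each centre
#' pixel to its quadrant corner; per corner a horizontal and a vertical
#' least-squares line are fitted and intersected; each intersection is then
#' refined by the intensity-weighted centre of gravity of the *original*
#' frame over a `(2 * refine_halfwidth + 1)^2` window.
#'
#' @param mask Logical matrix from [binarize_frame()].
#' @param frame The original (un-denoised) frame used for the weighted
#'   centre-of-gravity refinement.
#' @param refine_halfwidth Half-width in px of the refinement window. The
#'   default of 8 px covers the saturated spot plateau plus enough streak
#'   length to average out the half-pixel quantization of the thresholded
#'   runs; smaller windows localize slightly worse at every noise level.
#' @return An object of class `corner_set`: list with `corners` (4x2 matrix
#'   ordered tl, tr, br, bl), `intersections` (pre-refinement estimates) and
#'   `refinement_residual` (mean px distance between the two).
#' @export
locate_corners <- function(mask, frame, refine_halfwidth = 8) {
  if (!any(mask)) stop("corner localization failed: no edge pixels found",
                       call. = FALSE)
  idx <- which(mask, arr.ind = TRUE)
  cog <- colMeans(idx)  # (row, col) centre of gravity of the binary mask

  h_runs <- .filter_runs(.run_centres(mask, "col"))  # points on horiz. edges
  v_runs <- .filter_runs(.run_centres(mask, "row"))  # points on vert. edges
  if (nrow(h_runs) == 0 || nrow(v_runs) == 0) {
    stop("corner localization failed: no edge pixels found", call. = FALSE)
  }
  # (row, col) positions of edge-centre pixels
  h_pts <- cbind(row = h_runs$centre, col = h_runs$fixed)
  v_pts <- cbind(row = v_runs$fixed, col = v_runs$centre)

  quadrants <- list(
    tl = c(-1, -1), tr = c(-1, 1), br = c(1, 1), bl = c(1, -1)
  )
  inter <- matrix(NA_real_, 4, 2,
                  dimnames = list(names(quadrants), c("row", "col")))
  for (q in names(quadrants)) {
    s <- quadrants[[q]]
    hs <- h_pts[sign(h_pts[, "row"] - cog[1]) == s[1] &
                  sign(h_pts[, "col"] - cog[2]) == s[2], , drop = FALSE]
    vs <- v_pts[sign(v_pts[, "row"] - cog[1]) == s[1] &
                  sign(v_pts[, "col"] - cog[2]) == s[2], , drop = FALSE]
    ch <- .fit_line(hs[, "col"], hs[, "row"], paste0(q, " horizontal"))
    cv <- .fit_line(vs[, "row"], vs[, "col"], paste0(q, " vertical"))
    # row = ch1 + ch2 col ; col = cv1 + cv2 row
    denom <- 1 - ch[2] * cv[2]
    if (abs(denom) < 1e-9) {
      stop("corner localization failed at intersection (", q,
           "): fitted lines are parallel", call. = FALSE)
    }
    r <- (ch[1] + ch[2] * cv[1]) / denom
    inter[q, ] <- c(r, cv[1] + cv[2] * r)
  }

  refined <- inter
  for (q in rownames(inter)) {
    refined[q, ] <- refine_corner(frame, inter[q, ], refine_halfwidth)
  }

  cs <- structure(
    list(
      corners = refined,
      intersections = inter,
      refinement_residual = mean(sqrt(rowSums((refined - inter)^2)))
    ),
    class = "corner_set"
  )
  .check_corner_set(cs)
  cs
}

#' Weighted centre-of-gravity refinement of one corner
#'
#' Computes the intensity-weighted centre of gravity of the original frame
#' over a square window, then re-centres the window on the result and
#' repeats until the estimate is stable (a few iterations at most). The
#' re-centring removes the half-pixel bias a single fixed window inherits
#' from rounding its centre.
#'
#' @param frame Numeric matrix (original counts).
#' @param position Approximate (row, col) of the corner.
#' @param halfwidth Window half-width in px.
#' @param max_iter Maximum number of re-centring iterations.
#' @return Refined (row, col) position.
#' @export
refine_corner <- function(frame, position, halfwidth = 8, max_iter = 5) {
  pos <- position
  for (it in seq_len(max_iter)) {
    r0 <- round(pos[1])
    c0 <- round(pos[2])
    rs <- max(1, r0 - halfwidth):min(nrow(frame), r0 + halfwidth)
    cs <- max(1, c0 - halfwidth):min(ncol(frame), c0 + halfwidth)
    w <- frame[rs, cs, drop = FALSE]
    tot <- sum(w)
    if (tot <= 0) {
      stop("corner refinement failed: zero total intensity in window",
           call. = FALSE)
    }
    new <- c(row = sum(rowSums(w) * rs) / tot,
             col = sum(colSums(w) * cs) / tot)
    if (max(abs(round(new) - c(r0, c0))) < 1) {
      pos <- new
      break
    }
    pos <- new
  }
  pos
}

# Convexity + ordering sanity checks; aspect-ratio deviation only warns
# (the straight-line edge model degrades gracefully off-square).
.check_corner_set <- function(cs) {
  p <- cs$corners
  if (any(!is.finite(p))) {
    stop("corner localization failed: non-finite corner position",
         call. = FALSE)
  }
  n <- 4
  cr <- numeric(n)
  for (i in seq_len(n)) {
    a <- p[i %% n + 1, ] - p[i, ]
    b <- p[(i + 1) %% n + 1, ] - p[i %% n + 1, ]
    cr[i] <- a[1] * b[2] - a[2] * b[1]
  }
  if (any(cr == 0) || length(unique(sign(cr))) != 1) {
    stop("detected corners do not form a strictly convex quadrilateral",
         call. = FALSE)
  }
  sides <- sqrt(rowSums((p[c(2, 3, 4, 1), ] - p)^2))
  ratio <- max(sides) / min(sides)
  if (ratio > 1.25) {
    warning("detected pattern deviates from a square (side ratio ",
            sprintf("%.2f", ratio),
            "); straight-edge approximation may be poor", call. = FALSE)
  }
  invisible(cs)
}

#' Exact four-point homography onto canonical corners
#'
#' Solves the 8-unknown direct linear transform so that the detected corner
#' set maps exactly onto the canonical square. An affine-restricted mode
#' (6 degrees of freedom, least squares over the four correspondences) is
#' available for strictly affine drift.
#'
#' @param detected A `corner_set` or a 4x2 (row, col) matrix ordered
#'   tl, tr, br, bl.
#' @param canonical A 4x2 matrix of target positions in the same order,
#'   e.g. from [square_corners()].
#' @param method `"homography"` (default, 8 dof) or `"affine"` (6 dof).
#' @return An object of class `alignment_transform`: list with the 3x3
#'   `matrix` mapping source `(row, col, 1)` to canonical coordinates, and
#'   `canonical_corners`.
#' @export
compute_transform <- function(detected, canonical,
                              method = c("homography", "affine")) {
  method <- match.arg(method)
  if (inherits(detected, "corner_set")) detected <- detected$corners
  detected <- unname(as.matrix(detected))
  canonical <- unname(as.matrix(canonical))
  stopifnot(all(dim(detected) == c(4, 2)), all(dim(canonical) == c(4, 2)))
  .check_convex(detected, "detected")
  .check_convex(canonical, "canonical")

  if (method == "affine") {
    # (r', c') = A (r, c) + t, least squares over 4 correspondences
    X <- cbind(detected, 1)
    coef <- qr.solve(X, canonical)  # 3x2: canonical = [r, c, 1] %*% coef
    H <- rbind(t(coef), c(0, 0, 1))
  } else {
    A <- matrix(0, 8, 8)
    b <- numeric(8)
    for (i in 1:4) {
      r <- detected[i, 1]; c <- detected[i, 2]
      u <- canonical[i, 1]; v <- canonical[i, 2]
      A[2 * i - 1, ] <- c(r, c, 1, 0, 0, 0, -u * r, -u * c)
      A[2 * i, ]     <- c(0, 0, 0, r, c, 1, -v * r, -v * c)
      b[2 * i - 1] <- u
      b[2 * i] <- v
    }
    h <- tryCatch(solve(A, b), error = function(e) {
      stop("homography is degenerate for the given correspondences",
           call. = FALSE)
    })
    H <- matrix(c(h, 1), 3, 3, byrow = TRUE)
  }
  if (abs(det(H)) < 1e-12) {
    stop("computed transform is not invertible", call. = FALSE)
  }
  structure(list(matrix = H, canonical_corners = canonical, method = method),
            class = "alignment_transform")
}

.check_convex <- function(p, what) {
  n <- 4
  cr <- numeric(n)
  for (i in seq_len(n)) {
    a <- p[i %% n + 1, ] - p[i, ]
    b <- p[(i + 1) %% n + 1, ] - p[i %% n + 1, ]
    cr[i] <- a[1] * b[2] - a[2] * b[1]
  }
  if (any(cr == 0) || length(unique(sign(cr))) != 1) {
    stop(what, " corners are degenerate (not strictly convex)",
         call. = FALSE)
  }
}

#' Apply an alignment transform to points
#'
#' @param transform An `alignment_transform`.
#' @param points n x 2 matrix of (row, col) source positions.
#' @return n x 2 matrix of canonical positions.
#' @export
transform_points <- function(transform, points) {
  points <- rbind(points)
  ph <- transform$matrix %*% rbind(t(points), 1)
  out <- t(ph[1:2, , drop = FALSE] / rep(ph[3, ], each = 2))
  dimnames(out) <- dimnames(points)
  out
}

# Vectorized Catmull-Rom cubic sampling; coordinates outside the frame give
# 0 (edge pixels are clamp-replicated for the 4x4 support). Interpolates
# exactly at integer coordinates and smooths far less than bilinear.
.bicubic <- function(frame, r, c) {
  nr <- nrow(frame)
  nc <- ncol(frame)
  out <- numeric(length(r))
  ok <- r >= 1 & r <= nr & c >= 1 & c <= nc
  if (!any(ok)) return(out)
  r <- r[ok]; c <- c[ok]
  r0 <- floor(r); c0 <- floor(c)
  dr <- r - r0; dc <- c - c0
  w <- function(d) {
    # Catmull-Rom weights for offsets -1, 0, 1, 2 at fractional position d
    d2 <- d * d; d3 <- d2 * d
    cbind(-0.5 * d3 + d2 - 0.5 * d,
          1.5 * d3 - 2.5 * d2 + 1,
          -1.5 * d3 + 2 * d2 + 0.5 * d,
          0.5 * d3 - 0.5 * d2)
  }
  wr <- w(dr)
  wc <- w(dc)
  acc <- numeric(length(r))
  for (i in 1:4) {
    ri <- pmin(pmax(r0 + i - 2L, 1L), nr)
    row_val <- numeric(length(r))
    for (j in 1:4) {
      cj <- pmin(pmax(c0 + j - 2L, 1L), nc)
      row_val <- row_val + wc[, j] * frame[cbind(ri, cj)]
    }
    acc <- acc + wr[, i] * row_val
  }
  out[ok] <- acc
  out
}

# Vectorized bilinear sampling; coordinates outside the frame give 0.
.bilinear <- function(frame, r, c) {
  nr <- nrow(frame)
  nc <- ncol(frame)
  out <- numeric(length(r))
  ok <- r >= 1 & r <= nr & c >= 1 & c <= nc
  if (!any(ok)) return(out)
  r <- r[ok]; c <- c[ok]
  r0 <- floor(r); c0 <- floor(c)
  dr <- r - r0; dc <- c - c0
  r1 <- pmin(r0 + 1, nr); c1 <- pmin(c0 + 1, nc)
  f00 <- frame[cbind(r0, c0)]
  f01 <- frame[cbind(r0, c1)]
  f10 <- frame[cbind(r1, c0)]
  f11 <- frame[cbind(r1, c1)]
  out[ok] <- (1 - dr) * (1 - dc) * f00 + (1 - dr) * dc * f01 +
    dr * (1 - dc) * f10 + dr * dc * f11
  out
}

#' Warp a frame onto the canonical grid
#'
#' Resamples by inverse mapping with bilinear interpolation: each canonical
#' pixel is pulled from its source-frame position under the inverse
#' transform; pixels mapping outside the source are zero-filled. The
#' identity transform reproduces the input bit-exactly.
#'
#' @param frame Numeric source matrix.
#' @param transform An `alignment_transform` from [compute_transform()].
#' @param out_shape (rows, cols) of the output grid; defaults to the input
#'   shape.
#' @return The warped matrix.
#' @export
warp_frame <- function(frame, transform, out_shape = dim(frame)) {
  H <- transform$matrix
  if (abs(det(H)) < 1e-12) stop("transform is not invertible", call. = FALSE)
  Hinv <- solve(H)
  nr <- out_shape[1]
  nc <- out_shape[2]
  rr <- rep(seq_len(nr), times = nc)
  cc <- rep(seq_len(nc), each = nr)
  src <- Hinv %*% rbind(rr, cc, 1)
  sr <- src[1, ] / src[3, ]
  sc <- src[2, ] / src[3, ]
  # snap coordinates that are integers up to numerical noise, so an
  # identity (or integer-translation) transform reproduces pixel values
  # bit-exactly instead of blending in 1e-12-weighted neighbours
  sr <- ifelse(abs(sr - round(sr)) < 1e-9, round(sr), sr)
  sc <- ifelse(abs(sc - round(sc)) < 1e-9, round(sc), sc)
  matrix(.bilinear(frame, sr, sc), nr, nc)
}
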