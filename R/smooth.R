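#' Gaussian smoothing of a ratio image
#'
#' Separable 2-D Gaussian convolution with the kernel parameterized by its
#' half-width at half-maximum: `sigma = half_width / sqrt(2 ln 2)`
#' (half_width 5 px gives sigma ~ 4.246 px). Boundaries are handled by
#' symmetric reflection, so a constant image is returned unchanged and the
#' image mean is preserved.
#'
#' @param frame Numeric matrix (a single dR/R frame). All pixels must be
#'   finite.
#' @param half_width Kernel half-width at half-maximum, pixels (> 0).
#' @return Smoothed matrix of the same dimensions.
#' @export
smooth_frame <- function(frame, half_width = 5) {
  if (!is.matrix(frame)) stop("frame must be a matrix")
  if (half_width <= 0) stop("half_width must be > 0")
  if (!all(is.finite(frame))) stop("frame contains non-finite pixels")
  sigma <- half_width / sqrt(2 * log(2))
  r <- max(1L, ceiling(4 * sigma))
  g <- stats::dnorm(seq(-r, r), sd = sigma)
  g <- g / sum(g)
  out <- convolve_reflect(frame, g, r)          # along rows
  t(convolve_reflect(t(out), g, r))             # along columns
}

# 1-D convolution along the first dimension with symmetric reflection
convolve_reflect <- function(m, g, r) {
  n <- nrow(m)
  pre <- pmin(n, r:1)
  post <- pmax(1L, n:(n - r + 1L))
  mp <- m[c(pre, seq_len(n), post), , drop = FALSE]
  out <- matrix(0, n, ncol(m))
  for (j in seq_along(g))
    out <- out + g[j] * mp[j:(j + n - 1L), , drop = FALSE]
  out
}

#' Render a ratio frame for display
#'
#' Maps dR/R values to grayscale with symmetric clipping, the standard
#' display convention for intrinsic-signal ratio images (darker = dip,
#' brighter = overshoot).
#'
#' @param frame Numeric matrix of dR/R values.
#' @param clip Symmetric display limit (default 2.5e-4).
#' @param path Optional PNG output path.
#' @return Invisibly, the grayscale matrix in `[0, 1]`.
#' @export
render_ratio_frame <- function(frame, clip = 2.5e-4, path = NULL) {
  gray <- 0.5 + frame / (2 * clip)
  gray[gray < 0] <- 0
  gray[gray > 1] <- 1
  gray[is.na(gray)] <- 0.5
  if (!is.null(path)) png::writePNG(gray, path)
  invisible(gray)
}
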