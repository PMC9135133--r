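#' Gaussian count-correction filter
#'
#' Smooths a raw count matrix with a small discrete Gaussian, matching the
#' correction applied at acquisition (kernel size 3, sigma 1/3 pixel).
#' The result is re-quantized to integer counts by rounding and clipped to
#' the 16-bit range. Clinical images arrive already corrected, so this is an
#' optional preprocessing step; raw phantom output is typically passed
#' through it once.
#'
#' @param image A [scinti_image()].
#' @param kernel_size Odd kernel width (default 3).
#' @param sigma_px Gaussian sigma in pixels (default 1/3).
#' @return The smoothed `scinti_image`.
#' @export
gaussian_correct <- function(image, kernel_size = 3L, sigma_px = 1 / 3) {
  validate_scinti_image(image)
  kernel_size <- as.integer(kernel_size)
  if (kernel_size < 1L || kernel_size %% 2L == 0L)
    stop("kernel_size must be an odd integer >= 1")
  if (sigma_px <= 0) stop("sigma_px must be positive")
  k <- gaussian_kernel(kernel_size, sigma_px)
  # normalized convolution: divide by the local kernel mass so constants are
  # preserved exactly, including at the borders
  m <- matrix(as.double(image$pixels), nrow(image$pixels))
  p <- convolve2_zero(m, k) /
    convolve2_zero(matrix(1, nrow(m), ncol(m)), k)
  image$pixels <- matrix(as.integer(pmin(pmax(round(p), 0), 65535)),
                         nrow(image$pixels), ncol(image$pixels))
  image
}

gaussian_kernel <- function(size, sigma) {
  half <- (size - 1L) %/% 2L
  d <- seq(-half, half)
  k <- outer(exp(-d^2 / (2 * sigma^2)), exp(-d^2 / (2 * sigma^2)))
  k / sum(k)
}

# 2D convolution with zero padding, by shift-and-add (kernels here are tiny)
convolve2_zero <- function(m, k) {
  half <- (nrow(k) - 1L) %/% 2L
  H <- nrow(m); W <- ncol(m)
  out <- matrix(0, H, W)
  for (di in -half:half) {
    ri_dst <- max(1, 1 - di):min(H, H - di)
    ri_src <- ri_dst + di
    for (dj in -half:half) {
      w <- k[di + half + 1L, dj + half + 1L]
      if (w == 0) next
      cj_dst <- max(1, 1 - dj):min(W, W - dj)
      cj_src <- cj_dst + dj
      out[ri_dst, cj_dst] <- out[ri_dst, cj_dst] + w * m[ri_src, cj_src]
    }
  }
  out
}

#' Normalize a scintigram for network input
#'
#' Scales counts by the per-image maximum, yielding a single-channel map in
#' `[0, 1]` with maximum exactly 1. Per-image (rather than fixed 1/65535)
#' scaling absorbs the large patient-to-patient variation in global
#' radiotracer uptake. An all-zero scan returns an all-zero map with a
#' warning.
#'
#' @param image A [scinti_image()].
#' @return Numeric array of dimension `c(H, W, 1)` with values in `[0, 1]`.
#' @export
normalize_image <- function(image) {
  validate_scinti_image(image)
  p <- image$pixels
  mx <- max(p)
  if (mx == 0L) {
    warning("degenerate all-zero scan; returning all-zero map")
    out <- array(0, dim = c(dim(p), 1L))
  } else {
    out <- array(p / mx, dim = c(dim(p), 1L))
  }
  out
}

#' Export an 8-bit windowed PNG for visual inspection
#'
#' Intensity is windowed to the quantile range and gamma-compressed; this is
#' for eyeballing only and never feeds the network.
#'
#' @param image A [scinti_image()].
#' @param path PNG output path.
#' @param qhi Upper display quantile (default 0.999).
#' @return `path`, invisibly.
#' @export
export_png <- function(image, path, qhi = 0.999) {
  if (!requireNamespace("png", quietly = TRUE))
    stop("the 'png' package is required for PNG export")
  validate_scinti_image(image)
  p <- as.double(image$pixels)
  hi <- max(stats::quantile(p, qhi), 1)
  g <- pmin(p / hi, 1)^0.5
  png::writePNG(matrix(g, nrow(image$pixels)), path)
  invisible(path)
}
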