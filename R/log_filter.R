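#' Laplacian-of-Gaussian kernel
#'
#' Samples the LoG kernel
#' \deqn{f(x,y) = -\frac{1}{\pi\sigma^4}\left(1 -
#'   \frac{x^2+y^2}{2\sigma^2}\right) e^{-\frac{x^2+y^2}{2\sigma^2}}}
#' on an odd square grid of half-width \code{ceiling(radius_factor *
#' sigma)}. With this sign convention the kernel is negative at the
#' origin (\code{-1/(pi sigma^4)}), so bright ridges and blobs yield
#' strongly negative responses; segmentation thresholds the negated
#' response so that the cell interior is high.
#'
#' @param sigma Scale in pixels (> 0).
#' @param radius_factor Half-width of the support in units of sigma.
#' @return A square numeric matrix of odd size.
#' @export
log_kernel <- function(sigma, radius_factor = 4) {
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) ||
      sigma <= 0) {
    stop("'sigma' must be a single positive number", call. = FALSE)
  }
  r <- max(1L, as.integer(ceiling(radius_factor * sigma)))
  ax <- seq.int(-r, r)
  r2 <- outer(ax^2, ax^2, `+`)
  -1 / (pi * sigma^4) * (1 - r2 / (2 * sigma^2)) * exp(-r2 / (2 * sigma^2))
}

#' LoG-filter an image
#'
#' Convolves an image with the \code{\link{log_kernel}} using
#' replicate-padded spatial convolution. The response keeps the printed
#' kernel's sign: bright thin structures give negative values.
#'
#' @param image Numeric matrix (row = y, col = x).
#' @param sigma LoG scale in pixels.
#' @param radius_factor Kernel support half-width in units of sigma.
#' @return Numeric matrix of the same size as \code{image}.
#' @export
log_filter <- function(image, sigma, radius_factor = 4) {
  k <- log_kernel(sigma, radius_factor)
  if (min(dim(image)) < 3 * sigma) {
    stop("image too small for sigma = ", sigma,
         " (need at least 3*sigma pixels per side)", call. = FALSE)
  }
  convolve2_replicate(image, k)
}

# Spatial convolution with replicate boundary padding. The kernel is
# symmetric for the isotropic LoG, making convolution == correlation;
# directional half-kernels are symmetric under the 180-degree rotation
# applied here, so EBImage::filter2 (a correlation) is wrapped with an
# explicit kernel flip.
convolve2_replicate <- function(image, kernel) {
  k <- kernel[rev(seq_len(nrow(kernel))), rev(seq_len(ncol(kernel))), drop = FALSE]
  out <- EBImage::filter2(image, k, boundary = "replicate")
  m <- EBImage::imageData(out)
  dim(m) <- dim(image)
  m
}

#' Directional half-plane LoG kernels
#'
#' Builds eight one-sided LoG kernels by zeroing the half-plane behind
#' each of the eight principal directions (E, NE, N, NW, W, SW, S, SE).
#' Used by the adaptive thresholding mode.
#'
#' @inheritParams log_kernel
#' @return A list of eight numeric matrices.
#' @export
log_kernels_directional <- function(sigma, radius_factor = 4) {
  k <- log_kernel(sigma, radius_factor)
  r <- (nrow(k) - 1L) / 2L
  ax <- seq.int(-r, r)
  yy <- matrix(ax, nrow(k), ncol(k))          # row offset
  xx <- matrix(ax, nrow(k), ncol(k), byrow = TRUE)
  angles <- (0:7) * pi / 4
  lapply(angles, function(a) {
    keep <- cos(a) * xx - sin(a) * yy >= 0    # half-plane facing direction a
    k * keep
  })
}
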