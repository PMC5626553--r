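#' Auto-threshold method registry
#'
#' Histogram-based global auto-threshold algorithms available to
#' \code{\link{threshold_mask}}.
#'
#' @return Character vector of registered method names.
#' @export
threshold_methods <- function() {
  c("RenyiEntropy", "Huang", "Otsu", "Triangle", "Mean")
}

match_threshold_method <- function(method) {
  if (!is.character(method) || length(method) != 1L ||
      !(method %in% threshold_methods())) {
    stop("unknown threshold method '", paste(method, collapse = ","),
         "'; available: ", paste(threshold_methods(), collapse = ", "),
         call. = FALSE)
  }
  method
}

#' Auto-threshold a histogram
#'
#' Selects a threshold bin from a histogram of counts using one of the
#' registered algorithms. Foreground is defined as bins strictly above
#' the returned index.
#'
#' @param counts Non-negative integer vector of bin counts.
#' @param method One of \code{\link{threshold_methods}}.
#' @return Threshold bin index (1-based, into \code{counts}); pixels in
#'   bins above this index are foreground.
#' @export
auto_threshold_hist <- function(counts, method = "Otsu") {
  method <- match_threshold_method(method)
  stopifnot(is.numeric(counts), all(counts >= 0), sum(counts) > 0)
  switch(method,
         Otsu = th_otsu(counts),
         Huang = th_huang(counts),
         RenyiEntropy = th_renyi(counts),
         Triangle = th_triangle(counts),
         Mean = th_mean(counts))
}

#' Auto-threshold value for an image
#'
#' Histograms the image into \code{nbins} equal-width bins over its
#' finite range and applies \code{\link{auto_threshold_hist}}. Returns
#' a threshold on the intensity scale; foreground is
#' \code{image > value}.
#'
#' @param image Numeric matrix.
#' @param method One of \code{\link{threshold_methods}}.
#' @param nbins Number of histogram bins (256, as in 8-bit practice).
#' @return Threshold intensity (scalar).
#' @export
threshold_value <- function(image, method = "Otsu", nbins = 256L) {
  method <- match_threshold_method(method)
  v <- image[is.finite(image)]
  if (!length(v)) stop("image has no finite pixels", call. = FALSE)
  lo <- min(v); hi <- max(v)
  if (hi <= lo) return(lo)  # constant image: empty foreground
  edges <- seq(lo, hi, length.out = nbins + 1L)
  counts <- tabulate(pmin(pmax(findInterval(v, edges, rightmost.closed = TRUE),
                               1L), nbins), nbins)
  t_bin <- auto_threshold_hist(counts, method)
  edges[t_bin + 1L]  # upper edge of the threshold bin
}

#' Binarize a filtered image
#'
#' Thresholds a (typically negated-LoG-filtered) image with a
#' registered auto-threshold algorithm; the input polarity must put the
#' structures of interest high. With \code{adaptive = TRUE} the
#' original image is convolved with the eight directional half-plane
#' LoG kernels, each response is thresholded separately, the eight
#' masks are combined by pixelwise union, and a 3x3 median filter
#' removes speckle.
#'
#' @param filtered Numeric matrix to threshold (structures high).
#' @param method One of \code{\link{threshold_methods}}.
#' @param adaptive Logical; use the 8-directional variant.
#' @param image Raw image, required when \code{adaptive = TRUE}.
#' @param sigma LoG sigma, required when \code{adaptive = TRUE}.
#' @return Logical matrix (TRUE = foreground).
#' @export
threshold_mask <- function(filtered, method = "RenyiEntropy",
                           adaptive = FALSE, image = NULL, sigma = NULL) {
  method <- match_threshold_method(method)
  if (!adaptive) {
    return(filtered > threshold_value(filtered, method))
  }
  if (is.null(image) || is.null(sigma)) {
    stop("adaptive thresholding needs 'image' and 'sigma'", call. = FALSE)
  }
  kernels <- log_kernels_directional(sigma)
  mask <- matrix(FALSE, nrow(image), ncol(image))
  for (k in kernels) {
    resp <- -convolve2_replicate(image, k)  # structures high
    mask <- mask | (resp > threshold_value(resp, method))
  }
  md <- EBImage::medianFilter(EBImage::Image(mask * 1), size = 1L)
  EBImage::imageData(md) > 0.5
}

# ---- histogram algorithms -------------------------------------------------
# All operate on a counts vector; returned index t means bins > t are
# foreground. Formulations follow the standard auto-threshold library
# used in image analysis practice.

th_otsu <- function(counts) {
  n <- length(counts)
  p <- counts / sum(counts)
  i <- seq_len(n)
  w0 <- cumsum(p)
  mu <- cumsum(p * i)
  mu_t <- mu[n]
  w1 <- 1 - w0
  num <- (mu_t * w0 - mu)^2
  den <- w0 * w1
  bcv <- ifelse(den > 0, num / den, NA_real_)
  which.max(bcv)
}

th_mean <- function(counts) {
  i <- seq_along(counts)
  floor(sum(i * counts) / sum(counts))
}

th_huang <- function(counts) {
  # Huang & Wang fuzzy-entropy minimization
  first <- which(counts > 0)[1L]
  last <- tail(which(counts > 0), 1L)
  if (first == last) return(first)
  W <- cumsum(counts)
  S <- cumsum(counts * seq_along(counts))
  C <- last - first
  best <- Inf; best_t <- first
  for (t in first:(last - 1L)) {
    mu0 <- S[t] / W[t]
    wb <- W[last] - W[t]
    mu1 <- (S[last] - S[t]) / wb
    ent <- 0
    for (i in first:last) {
      mu_x <- 1 / (1 + abs(i - (if (i <= t) mu0 else mu1)) / C)
      if (mu_x > 1e-12 && mu_x < 1 - 1e-12) {
        ent <- ent + counts[i] *
          (-mu_x * log(mu_x) - (1 - mu_x) * log(1 - mu_x))
      }
    }
    if (ent < best) { best <- ent; best_t <- t }
  }
  best_t
}

th_triangle <- function(counts) {
  # Triangle method: maximal distance between the histogram and the
  # line from the low end to the peak; the histogram is flipped first
  # if the long tail lies to the right, so the scan always runs along
  # the long-tail side.
  n <- length(counts)
  lo <- max(which(counts > 0)[1L] - 1L, 1L)
  hi <- min(tail(which(counts > 0), 1L) + 1L, n)
  peak <- which.max(counts)
  inverted <- (peak - lo) < (hi - peak)
  h <- counts
  if (inverted) {
    h <- rev(h)
    lo <- n + 1L - hi
    peak <- n + 1L - peak
  }
  if (lo == peak) return(if (inverted) n + 1L - lo else lo)
  nx <- h[peak]; ny <- lo - peak
  d <- sqrt(nx^2 + ny^2); nx <- nx / d; ny <- ny / d
  dconst <- nx * lo + ny * h[lo]
  split <- lo; split_d <- 0
  for (i in (lo + 1L):peak) {
    dd <- nx * i + ny * h[i] - dconst
    if (dd > split_d) { split_d <- dd; split <- i }
  }
  split <- split - 1L
  if (inverted) n - split else split
}

th_renyi <- function(counts) {
  # Renyi-entropy method: maximum-entropy thresholds at orders
  # 1/2, 1 (Shannon) and 2, combined with order-dependent weights.
  p <- counts / sum(counts)
  n <- length(p)
  P1 <- cumsum(p)
  P2 <- 1 - P1
  nz <- which(p > 0)
  first <- nz[1L]; last <- tail(nz, 1L)
  if (first == last) return(first)
  ok <- seq_len(n) >= first & seq_len(n) < last & P1 > 2.2e-16 & P2 > 2.2e-16
  cand <- which(ok)
  ent_at <- function(t, q) {
    fg <- p[first:t] / P1[t]
    bg <- p[(t + 1L):last] / P2[t]
    fg <- fg[fg > 0]; bg <- bg[bg > 0]
    if (q == 1) {
      -sum(fg * log(fg)) - sum(bg * log(bg))
    } else {
      log(sum(fg^q)) / (1 - q) + log(sum(bg^q)) / (1 - q)
    }
  }
  pick <- function(q) cand[which.max(vapply(cand, ent_at, 0, q = q))]
  ts <- sort(c(pick(0.5), pick(1), pick(2)))
  t1 <- ts[1L]; t2 <- ts[2L]; t3 <- ts[3L]
  if (abs(t1 - t2) <= 5) {
    if (abs(t2 - t3) <= 5) { b <- c(1, 2, 1) } else { b <- c(0, 1, 3) }
  } else {
    if (abs(t2 - t3) <= 5) { b <- c(3, 1, 0) } else { b <- c(1, 2, 1) }
  }
  omega <- P1[t3] - P1[t1]
  t_opt <- t1 * (P1[t1] + 0.25 * omega * b[1L]) +
    0.25 * t2 * omega * b[2L] +
    t3 * (P2[t3] + 0.25 * omega * b[3L])
  max(1L, min(n, as.integer(round(t_opt))))
}
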