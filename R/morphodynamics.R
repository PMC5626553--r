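#' End-corrected protrusion length
#'
#' Length is estimated as half the protrusion mask perimeter minus an
#' end correction. Half the perimeter of a capsule-shaped mask counts
#' the two sides, the tip cap and the base edge; relative to the true
#' base-to-tip extent this overestimates by the cap's half-arc excess
#' (pi - 2) w / 4 plus half the base edge w / 2, i.e. pi w / 4 in
#' total, where \code{w = 2 sqrt(2 ln 2) sigma px} is the
#' full-width-at-half-maximum width. The correction is scaled by
#' \code{min[(D/w)^2, 1]} so that protrusions wider than their
#' base-tip distance D are corrected less.
#'
#' @param geom A \code{protrusion_geometry}.
#' @param params A \code{\link{segmentation_params}} (sigma and pixel
#'   size).
#' @param correction_const Correction in units of w; default
#'   \code{pi/4}, validated against rasterized capsules of known
#'   length.
#' @return Length in micrometres.
#' @export
corrected_length <- function(geom, params = segmentation_params(),
                             correction_const = pi / 4) {
  if (isTRUE(geom$flagged) || is.na(geom$perimeter_px)) return(NA_real_)
  w <- geom$width_w_px
  scale <- min((geom$euclidean_D / w)^2, 1)
  len_px <- geom$perimeter_px / 2 - correction_const * w * scale
  max(len_px, 0) * params$pixel_size_nm / 1000
}

#' Straightness and waviness
#'
#' \code{straightness = D / length} (base-tip Euclidean distance over
#' corrected length) and \code{waviness = 1 - straightness}. Both are
#' unreliable for protrusions shorter than about twice the width w;
#' such values are flagged.
#'
#' @param geom A \code{protrusion_geometry}.
#' @param length_um Corrected length in micrometres.
#' @param params A \code{\link{segmentation_params}}.
#' @return List with \code{straightness}, \code{waviness},
#'   \code{flagged}.
#' @export
straightness <- function(geom, length_um, params = segmentation_params()) {
  if (is.na(length_um) || length_um <= 0) {
    return(list(straightness = NA_real_, waviness = NA_real_, flagged = TRUE))
  }
  d_um <- geom$euclidean_D * params$pixel_size_nm / 1000
  s <- d_um / length_um
  w_um <- geom$width_w_px * params$pixel_size_nm / 1000
  list(straightness = s, waviness = 1 - s, flagged = length_um < 2 * w_um)
}

#' Direction-corrected tip and base movement
#'
#' DCTM is the tip displacement from the preceding time point projected
#' onto the current base-to-tip axis; DCBM is the analogous projection
#' of the base displacement. Both are converted to nm/s using the
#' calibration. The projection removes apparent speed caused by
#' sideways swinging, so DCTM tracks the extension/retraction rate
#' along the filopodium axis (assuming no retrograde flow). The first
#' frame, frames after a gap, and frames with a degenerate (tip ==
#' base) axis yield NA.
#'
#' @param track A track (list with \code{frames} and \code{geoms}).
#' @param params A \code{\link{segmentation_params}}.
#' @return Data frame with \code{frame}, \code{dctm_nm_s},
#'   \code{dcbm_nm_s}.
#' @export
directional_movement <- function(track, params = segmentation_params()) {
  n <- length(track$frames)
  dctm <- rep(NA_real_, n)
  dcbm <- rep(NA_real_, n)
  if (n >= 2) {
    for (i in 2:n) {
      if (track$frames[i] - track$frames[i - 1] != 1L) next
      g1 <- track$geoms[[i - 1]]; g2 <- track$geoms[[i]]
      if (any(is.na(g1$tip_xy)) || any(is.na(g2$tip_xy))) next
      axis <- g2$tip_xy - g2$base_xy
      len <- sqrt(sum(axis^2))
      if (len == 0) next
      u <- axis / len
      scale <- params$pixel_size_nm / params$frame_interval_s
      dctm[i] <- sum((g2$tip_xy - g1$tip_xy) * u) * scale
      dcbm[i] <- sum((g2$base_xy - g1$base_xy) * u) * scale
    }
  }
  data.frame(frame = track$frames, dctm_nm_s = dctm, dcbm_nm_s = dcbm)
}

#' Percentile filter and rolling mean for movement series
#'
#' Replaces values outside the [p_low, p_high] percentile range of the
#' series with NA (rejecting out-of-focus spikes and reconstruction
#' errors), then applies a centered rolling mean whose window is
#' truncated at the series ends; NAs are ignored within each window
#' but all-NA windows stay NA.
#'
#' @param x Numeric series (NAs allowed).
#' @param params An \code{\link{analysis_params}}.
#' @return Numeric series of the same length.
#' @export
preprocess_series <- function(x, params = analysis_params()) {
  if (!length(x)) return(x)
  q <- quantile(x, c(params$percentile_low, params$percentile_high) / 100,
                na.rm = TRUE, names = FALSE)
  y <- ifelse(!is.na(x) & (x < q[1] | x > q[2]), NA_real_, x)
  rolling_mean(y, params$rolling_window)
}

# centered rolling mean, window truncated at ends, NA-tolerant
rolling_mean <- function(x, k) {
  n <- length(x)
  h <- (k - 1L) %/% 2L
  out <- vapply(seq_len(n), function(i) {
    w <- x[max(1L, i - h):min(n, i + h)]
    if (all(is.na(w))) NA_real_ else mean(w, na.rm = TRUE)
  }, 0)
  out
}

#' Classify tip and base movement states
#'
#' The smoothed movement series is averaged over a centered window of
#' \code{state_window_s} seconds and compared with the
#' +/-\code{state_threshold_nm_s} threshold: above it the tip is
#' extending (base: invading), below the negative threshold retracting,
#' otherwise stalling (base: stable). Windows touching missing values
#' are unclassified. Fractions are computed over classified frames.
#'
#' @param dctm_series,dcbm_series Smoothed movement series in nm/s
#'   (from \code{\link{preprocess_series}}).
#' @param params An \code{\link{analysis_params}}.
#' @param frame_interval_s Frame interval in seconds.
#' @return List with \code{tip_state}, \code{base_state} (character
#'   vectors) and the six time fractions.
#' @export
classify_states <- function(dctm_series, dcbm_series,
                            params = analysis_params(),
                            frame_interval_s = 2) {
  w <- max(1L, round(params$state_window_s / frame_interval_s))
  thr <- params$state_threshold_nm_s
  class_one <- function(x, labels) {
    n <- length(x)
    if (n < w) return(rep(NA_character_, n))
    h <- (w - 1L) %/% 2L
    vapply(seq_len(n), function(i) {
      lo <- i - h; hi <- i + (w - 1L - h)
      if (lo < 1L || hi > n) return(NA_character_)
      m <- mean(x[lo:hi])  # NA propagates: missing frames unclassified
      if (is.na(m)) NA_character_
      else if (m > thr) labels[1]
      else if (m < -thr) labels[2]
      else labels[3]
    }, "")
  }
  tip <- class_one(dctm_series, c("extending", "retracting", "stalling"))
  base <- class_one(dcbm_series, c("invading", "retracting", "stable"))
  frac <- function(s, lab) {
    k <- sum(!is.na(s))
    if (k == 0) NA_real_ else sum(s == lab, na.rm = TRUE) / k
  }
  list(tip_state = tip, base_state = base,
       frac_extending = frac(tip, "extending"),
       frac_retracting = frac(tip, "retracting"),
       frac_stalling = frac(tip, "stalling"),
       frac_base_invading = frac(base, "invading"),
       frac_base_retracting = frac(base, "retracting"),
       frac_base_stable = frac(base, "stable"))
}

#' Tip persistence
#'
#' Time for the sample autocorrelation of the (smoothed) tip movement
#' series to first drop to zero, with linear interpolation between
#' integer lags, in seconds. If the ACF never crosses zero within the
#' available lags, the maximum lag is returned and the result is
#' flagged censored.
#'
#' @param dctm_series Smoothed tip movement series (nm/s); NAs are
#'   dropped before the ACF.
#' @param params An \code{\link{analysis_params}}.
#' @param frame_interval_s Frame interval in seconds.
#' @return List with \code{persistence_s}, \code{censored},
#'   \code{flagged}.
#' @export
tip_persistence <- function(dctm_series, params = analysis_params(),
                            frame_interval_s = 2) {
  x <- dctm_series[!is.na(dctm_series)]
  if (length(x) < 4 || sd(x) == 0) {
    return(list(persistence_s = NA_real_, censored = FALSE, flagged = TRUE))
  }
  a <- as.numeric(acf(x, lag.max = length(x) - 1L, plot = FALSE,
                      demean = TRUE)$acf)
  for (k in seq.int(2L, length(a))) {
    if (a[k] <= 0) {
      lag0 <- (k - 2L) + a[k - 1L] / (a[k - 1L] - a[k])
      return(list(persistence_s = lag0 * frame_interval_s,
                  censored = FALSE, flagged = FALSE))
    }
  }
  list(persistence_s = (length(a) - 1L) * frame_interval_s,
       censored = TRUE, flagged = FALSE)
}

# linear pixel indices of a disk, clipped to the image
disk_pixels <- function(center, radius, dims) {
  rows <- max(1, floor(center[1] - radius)):min(dims[1], ceiling(center[1] + radius))
  cols <- max(1, floor(center[2] - radius)):min(dims[2], ceiling(center[2] + radius))
  g <- expand.grid(row = rows, col = cols)
  g <- g[(g$row - center[1])^2 + (g$col - center[2])^2 <= radius^2, ]
  g$row + (g$col - 1L) * dims[1]
}

# mean intensity of a background annulus just outside the cell mask
background_mean <- function(seg, image, gap = 2L, width = 3L) {
  cell <- seg$mask | seg$body_mask
  inner <- morph_n(cell, EBImage::dilate, gap)
  outer_m <- morph_n(inner, EBImage::dilate, width)
  ring <- outer_m & !inner
  if (!any(ring)) return(NA_real_)
  mean(image[ring])
}

#' Fluorescence means for one protrusion
#'
#' Computes the measurement-channel means used downstream: projection
#' mean (whole protrusion mask), tip mean and Otsu-thresholded tip mean
#' (disk of radius \code{tip_radius_px} at the tip), base mean (same
#' disk at the base), body mean, and a background estimate from a
#' 3-px annulus starting 2 px outside the cell mask. Normalized values
#' are background-subtracted ratios to the background-subtracted body
#' mean; they are NA (flagged) when body does not exceed background.
#'
#' @param seg A \code{frame_segmentation}.
#' @param geom A \code{protrusion_geometry}.
#' @param measurement_image Numeric matrix.
#' @return List of fluorescence fields.
#' @export
measure_fluorescence <- function(seg, geom, measurement_image) {
  dims <- dim(measurement_image)
  pix <- which(seg$protrusion_labels == geom$label)
  proj_mean <- mean(measurement_image[pix])
  r <- geom$tip_radius_px
  tip_pix <- disk_pixels(geom$tip_xy, r, dims)
  base_pix <- disk_pixels(geom$base_xy, r, dims)
  tip_mean <- if (length(tip_pix)) mean(measurement_image[tip_pix]) else NA_real_
  base_mean <- if (length(base_pix)) mean(measurement_image[base_pix]) else NA_real_
  tip_thresh_mean <- NA_real_
  if (length(tip_pix)) {
    v <- measurement_image[tip_pix]
    if (length(unique(v)) > 1) {
      thr <- threshold_value(matrix(v, 1), "Otsu")
      if (any(v > thr)) tip_thresh_mean <- mean(v[v > thr])
    } else tip_thresh_mean <- mean(v)
  }
  body_mean <- mean(measurement_image[seg$body_mask])
  bg <- background_mean(seg, measurement_image)
  denom <- body_mean - bg
  norm <- function(x) if (is.na(denom) || denom <= 0) NA_real_ else (x - bg) / denom
  list(proj_mean = proj_mean, base_mean = base_mean, tip_mean = tip_mean,
       tip_thresh_mean = tip_thresh_mean, body_mean = body_mean,
       background = bg,
       normalized_tip = norm(tip_thresh_mean),
       normalized_base = norm(base_mean),
       normalized_flagged = is.na(denom) || denom <= 0)
}

#' Pre-formation base position and fluorescence
#'
#' Walks backwards from a track's formation frame: in each earlier
#' frame the predicted base is the boundary point closest to the
#' (predicted) base of the following frame. The base-disk fluorescence
#' is measured there and normalized against that frame's body and
#' background. The pre-formation summary is the mean normalized value
#' of the last \code{preformation_points} frames before formation.
#'
#' @param track A track whose first frame is its formation frame.
#' @param segs List of per-frame \code{frame_segmentation}.
#' @param measurement_images List of per-frame matrices.
#' @param params A \code{\link{segmentation_params}}
#'   (\code{base_back_frames}).
#' @param aparams An \code{\link{analysis_params}}.
#' @return List with \code{table} (frame, row, col, base_mean,
#'   normalized_base) and \code{preformation_mean}.
#' @export
predicted_base_fluorescence <- function(track, segs, measurement_images,
                                        params = segmentation_params(),
                                        aparams = analysis_params()) {
  t0 <- track$frames[1]
  if (t0 <= 1L) {
    return(list(table = NULL, preformation_mean = NA_real_,
                reason = "formation not observed (track starts at frame 1)"))
  }
  ref <- track$geoms[[1]]$base_xy
  rows <- integer(0); cols <- integer(0)
  bmeans <- numeric(0); nmeans <- numeric(0); frames <- integer(0)
  r <- track$geoms[[1]]$tip_radius_px
  back <- seq.int(t0 - 1L, by = -1L,
                  length.out = min(params$base_back_frames, t0 - 1L))
  for (t in back) {
    bd <- segs[[t]]$boundary
    if (!nrow(bd)) break
    d2 <- (bd[, 1] - ref[1])^2 + (bd[, 2] - ref[2])^2
    p <- as.numeric(bd[which.min(d2), ])
    img <- measurement_images[[t]]
    pix <- disk_pixels(p, r, dim(img))
    bm <- if (length(pix)) mean(img[pix]) else NA_real_
    body <- mean(img[segs[[t]]$body_mask])
    bg <- background_mean(segs[[t]], img)
    nm <- if (!is.na(bg) && body - bg > 0) (bm - bg) / (body - bg) else NA_real_
    frames <- c(frames, t); rows <- c(rows, p[1]); cols <- c(cols, p[2])
    bmeans <- c(bmeans, bm); nmeans <- c(nmeans, nm)
    ref <- p
  }
  tab <- data.frame(frame = frames, row = rows, col = cols,
                    base_mean = bmeans, normalized_base = nmeans)
  tab <- tab[order(tab$frame), , drop = FALSE]
  k <- aparams$preformation_points
  pre <- tail(tab$normalized_base, k)
  list(table = tab,
       preformation_mean = if (length(pre)) mean(pre, na.rm = TRUE) else NA_real_)
}

#' Boundary intensity and velocity profile
#'
#' Resamples each frame's body boundary to a fixed number of points.
#' Intensity is the mean of a small disk just inside the boundary;
#' velocity is a proxy for local boundary movement, taken as the
#' temporal change of raw intensity at the fixed boundary coordinate
#' (centered difference, per second). For a bright cell on a dark
#' background an advancing boundary covers the point, so positive
#' values mean outward movement.
#'
#' @param segs List of per-frame \code{frame_segmentation}.
#' @param image_stack List of per-frame raw matrices (same channel the
#'   boundary is measured in).
#' @param n_points Number of boundary samples per frame.
#' @param radius Radius of the internal sampling disk, px.
#' @param frame_interval_s Frame interval in seconds.
#' @return Data frame (frame, point, row, col, intensity, velocity).
#' @export
boundary_profile <- function(segs, image_stack, n_points = 100L,
                             radius = 2, frame_interval_s = 2) {
  stopifnot(length(segs) >= 2, length(segs) == length(image_stack))
  nT <- length(segs)
  out <- vector("list", nT)
  for (t in seq_len(nT)) {
    bd <- segs[[t]]$boundary
    idx <- round(seq(1, nrow(bd), length.out = n_points + 1L))[-(n_points + 1L)]
    pts <- bd[idx, , drop = FALSE]
    img <- image_stack[[t]]
    intensity <- vapply(seq_len(n_points), function(i) {
      pix <- disk_pixels(pts[i, ], radius, dim(img))
      pix <- pix[(segs[[t]]$mask | segs[[t]]$body_mask)[pix]]
      if (length(pix)) mean(img[pix]) else NA_real_
    }, 0)
    velocity <- rep(NA_real_, n_points)
    if (t > 1 && t < nT) {
      i0 <- image_stack[[t - 1]]; i1 <- image_stack[[t + 1]]
      velocity <- (i1[pts] - i0[pts]) / (2 * frame_interval_s)
    }
    out[[t]] <- data.frame(frame = t, point = seq_len(n_points),
                           row = pts[, 1], col = pts[, 2],
                           intensity = intensity, velocity = velocity)
  }
  do.call(rbind, out)
}

#' Per-frame metrics table for one track
#'
#' Assembles the standard per-frame metrics: corrected length, dL,
#' DCTM, DCBM, straightness/waviness, and (when measurement images are
#' given) the fluorescence panel. Frames missing from the track (gaps)
#' contribute no rows; metrics that straddle a gap are NA.
#'
#' @param track A track.
#' @param params A \code{\link{segmentation_params}}.
#' @param segs Optional list of \code{frame_segmentation} (needed for
#'   fluorescence).
#' @param measurement_images Optional list of matrices.
#' @return Data frame, one row per track frame.
#' @export
track_metrics <- function(track, params = segmentation_params(),
                          segs = NULL, measurement_images = NULL) {
  n <- length(track$frames)
  len <- vapply(track$geoms, corrected_length, 0, params = params)
  st <- lapply(seq_len(n), function(i)
    straightness(track$geoms[[i]], len[i], params))
  dl <- c(NA_real_, diff(len))
  gap <- c(TRUE, diff(track$frames) != 1L)
  dl[gap] <- NA_real_
  mv <- directional_movement(track, params)
  tab <- data.frame(
    track_id = track$track_id,
    frame = track$frames,
    time_s = (track$frames - 1L) * params$frame_interval_s,
    length_um = len,
    dL_um = dl,
    dctm_nm_s = mv$dctm_nm_s,
    dcbm_nm_s = mv$dcbm_nm_s,
    straightness = vapply(st, `[[`, 0, "straightness"),
    waviness = vapply(st, `[[`, 0, "waviness"),
    base_row = vapply(track$geoms, function(g) g$base_xy[1], 0),
    base_col = vapply(track$geoms, function(g) g$base_xy[2], 0),
    tip_row = vapply(track$geoms, function(g) g$tip_xy[1], 0),
    tip_col = vapply(track$geoms, function(g) g$tip_xy[2], 0)
  )
  if (!is.null(segs) && !is.null(measurement_images)) {
    fl <- lapply(seq_len(n), function(i) {
      t <- track$frames[i]
      measure_fluorescence(segs[[t]], track$geoms[[i]],
                           measurement_images[[t]])
    })
    for (f in c("proj_mean", "base_mean", "tip_mean", "tip_thresh_mean",
                "body_mean", "background", "normalized_tip",
                "normalized_base")) {
      tab[[f]] <- vapply(fl, function(x) as.numeric(x[[f]]), 0)
    }
  }
  tab
}
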