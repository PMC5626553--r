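#' Specification for a synthetic growth-cone movie
#'
#' Describes a bright cell body with thin dynamic protrusions in a
#' mapping channel and tip-enriched fluorescence in a measurement
#' channel, emulating the imaging regime of growth-cone time-lapse
#' microscopy (65 nm pixels, 2 s frames by default). All intensities
#' are integer camera counts; noise is additive Gaussian (rounded).
#'
#' @param width,height Image size in pixels.
#' @param n_frames Number of time points.
#' @param pixel_size_nm,frame_interval_s Calibration.
#' @param body_center (row, col) of the body disk.
#' @param body_radius_px Body disk radius.
#' @param body_jitter_px Per-frame s.d. of the body centre jitter.
#' @param background,body_level,protrusion_level Mapping-channel
#'   intensity levels (counts).
#' @param noise_sd Gaussian noise s.d. (counts), both channels.
#' @param meas_background,meas_body_level Measurement-channel levels.
#' @param tip_amplitude Peak tip-spot amplitude in the measurement
#'   channel.
#' @param tip_sigma_px Tip-spot Gaussian s.d.
#' @param preformation_frames Frames before nucleation over which a
#'   boundary spot ramps up linearly at the future base position.
#' @param filopodia List of per-filopodium specs; each a list with
#'   \code{nucleation_frame}, \code{angle_deg}, \code{width_px},
#'   \code{initial_length_um}, \code{velocity_nm_s} (scalar or
#'   per-frame vector), \code{drift_deg_per_frame}.
#' @param seed Mandatory integer seed.
#' @return An object of class \code{movie_spec}.
#' @export
movie_spec <- function(width = 220L, height = 220L, n_frames = 30L,
                       pixel_size_nm = 65, frame_interval_s = 2,
                       body_center = c(height / 2, width / 2),
                       body_radius_px = 32,
                       body_jitter_px = 0,
                       background = 10, body_level = 200,
                       protrusion_level = 180, noise_sd = 4,
                       meas_background = 8, meas_body_level = 100,
                       tip_amplitude = 150, tip_sigma_px = 2,
                       preformation_frames = 0L,
                       filopodia = list(), seed) {
  if (missing(seed)) stop("'seed' is mandatory", call. = FALSE)
  filopodia <- lapply(filopodia, function(f) {
    defaults <- list(nucleation_frame = 1L, angle_deg = 0,
                     width_px = 5, initial_length_um = 1,
                     velocity_nm_s = 0, drift_deg_per_frame = 0)
    defaults[names(f)] <- f
    defaults
  })
  structure(list(width = as.integer(width), height = as.integer(height),
                 n_frames = as.integer(n_frames),
                 pixel_size_nm = pixel_size_nm,
                 frame_interval_s = frame_interval_s,
                 body_center = body_center,
                 body_radius_px = body_radius_px,
                 body_jitter_px = body_jitter_px,
                 background = background, body_level = body_level,
                 protrusion_level = protrusion_level, noise_sd = noise_sd,
                 meas_background = meas_background,
                 meas_body_level = meas_body_level,
                 tip_amplitude = tip_amplitude,
                 tip_sigma_px = tip_sigma_px,
                 preformation_frames = as.integer(preformation_frames),
                 filopodia = filopodia, seed = as.integer(seed)),
            class = "movie_spec")
}

# distance from every pixel to a segment; used to rasterize capsules
segment_distance <- function(rows, cols, p0, p1) {
  d <- p1 - p0
  len2 <- sum(d^2)
  pr <- outer(rows - p0[1], rep(1, length(cols)))
  pc <- outer(rep(1, length(rows)), cols - p0[2])
  if (len2 == 0) return(sqrt(pr^2 + pc^2))
  t <- (pr * d[1] + pc * d[2]) / len2
  t <- pmin(pmax(t, 0), 1)
  sqrt((pr - t * d[1])^2 + (pc - t * d[2])^2)
}

gaussian_spot <- function(rows, cols, center, sigma, amplitude) {
  d2 <- outer((rows - center[1])^2, rep(1, length(cols))) +
    outer(rep(1, length(rows)), (cols - center[2])^2)
  amplitude * exp(-d2 / (2 * sigma^2))
}

#' Generate a synthetic two-channel movie with ground truth
#'
#' Rasterizes the body disk and capsule-shaped filopodia
#' (rectangle + semicircular cap: the geometry the length correction
#' is derived from) into a mapping channel, and body-level plus
#' tip-localized Gaussian spots (with optional pre-formation boundary
#' accumulation) into a measurement channel. Deterministic given the
#' spec's seed. Ground truth (base, tip, length, tip velocity,
#' identity) is computed analytically before rasterization.
#'
#' @param spec A \code{\link{movie_spec}}.
#' @return List with \code{mapping} and \code{measurement} (lists of
#'   integer matrices), \code{truth} (data frame), \code{spec}.
#' @export
generate_movie <- function(spec) {
  stopifnot(inherits(spec, "movie_spec"))
  set.seed(spec$seed)
  rows <- seq_len(spec$height); cols <- seq_len(spec$width)
  px <- spec$pixel_size_nm
  jit <- if (spec$body_jitter_px > 0) {
    matrix(rnorm(2 * spec$n_frames, 0, spec$body_jitter_px),
           spec$n_frames, 2)
  } else matrix(0, spec$n_frames, 2)
  # analytic truth first
  truth <- list()
  filo_state <- lapply(spec$filopodia, function(f) {
    v <- rep_len(f$velocity_nm_s, spec$n_frames)
    f$length_um_t <- rep(NA_real_, spec$n_frames)
    active <- f$nucleation_frame:spec$n_frames
    lens <- f$initial_length_um +
      cumsum(c(0, v[active[-length(active)]])) *
        spec$frame_interval_s / 1000
    f$length_um_t[active] <- pmax(lens, 0.1)
    f$velocity_t <- v
    f
  })
  mapping <- vector("list", spec$n_frames)
  measurement <- vector("list", spec$n_frames)
  for (t in seq_len(spec$n_frames)) {
    ctr <- spec$body_center + jit[t, ]
    d2body <- outer((rows - ctr[1])^2, rep(1, length(cols))) +
      outer(rep(1, length(rows)), (cols - ctr[2])^2)
    body <- d2body <= spec$body_radius_px^2
    map <- matrix(spec$background, spec$height, spec$width)
    map[body] <- spec$body_level
    meas <- matrix(spec$meas_background, spec$height, spec$width)
    meas[body] <- spec$meas_body_level
    for (i in seq_along(filo_state)) {
      f <- filo_state[[i]]
      ang <- (f$angle_deg + f$drift_deg_per_frame *
                (t - f$nucleation_frame)) * pi / 180
      dir <- c(-cos(ang), sin(ang))  # angle 0 points up the image
      base <- ctr + spec$body_radius_px * dir
      if (t < f$nucleation_frame) {
        # pre-formation accumulation at the future base position
        k <- f$nucleation_frame - t
        if (spec$preformation_frames > 0 && k <= spec$preformation_frames) {
          amp <- spec$tip_amplitude * (1 - k / (spec$preformation_frames + 1))
          meas <- meas + gaussian_spot(rows, cols, base,
                                       spec$tip_sigma_px, amp)
        }
        next
      }
      len_px <- f$length_um_t[t] * 1000 / px
      half_w <- f$width_px / 2
      tip_ext <- base + len_px * dir            # tip extremity
      seg_end <- base + max(len_px - half_w, 0) * dir
      if (any(tip_ext < 1 + half_w) ||
          tip_ext[1] > spec$height - half_w ||
          tip_ext[2] > spec$width - half_w) {
        stop("filopodium ", i, " exits the frame at t = ", t, call. = FALSE)
      }
      dmat <- segment_distance(rows, cols, base, seg_end)
      capsule <- dmat <= half_w & !body
      map[capsule] <- spec$protrusion_level
      meas <- meas + gaussian_spot(rows, cols, tip_ext,
                                   spec$tip_sigma_px, spec$tip_amplitude)
      truth[[length(truth) + 1L]] <- data.frame(
        frame = t, filo_id = i,
        base_row = base[1], base_col = base[2],
        tip_row = tip_ext[1], tip_col = tip_ext[2],
        length_um = f$length_um_t[t],
        tip_velocity_nm_s = if (t > f$nucleation_frame)
          f$velocity_t[t - 1L] else NA_real_)
    }
    if (spec$noise_sd > 0) {
      map <- map + rnorm(length(map), 0, spec$noise_sd)
      meas <- meas + rnorm(length(meas), 0, spec$noise_sd)
    }
    mapping[[t]] <- matrix(pmax(round(map), 0L), spec$height, spec$width)
    measurement[[t]] <- matrix(pmax(round(meas), 0L), spec$height,
                               spec$width)
  }
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(frame = integer(0), filo_id = integer(0))
  list(mapping = mapping, measurement = measurement, truth = truth,
       spec = spec)
}

# standardized AR(1) series
ar1_series <- function(n, phi, burn = 50L) {
  e <- rnorm(n + burn)
  x <- as.numeric(stats::filter(e, phi, method = "recursive"))
  x <- x[(burn + 1):(burn + n)]
  (x - mean(x)) / sd(x)
}

#' Generate a coupled fluorescence/movement series pair
#'
#' Movement is an AR(1) process; fluorescence is
#' \code{coupling * movement(t + lag) + sqrt(1 - coupling^2) * noise},
#' where the noise is an independent AR(1) process, so that the
#' population cross-correlation at the configured lag equals
#' \code{coupling}. A positive \code{lag_frames} makes fluorescence
#' lead movement (the CCF then peaks at a negative offset). A
#' statistical stand-in for tip-reporter data with known coupling.
#'
#' @param n_points Series length (>= 17, the cross-correlation
#'   minimum).
#' @param coupling Coupling coefficient in [0, 1].
#' @param ar_coeff AR(1) coefficient, |ar_coeff| < 1.
#' @param noise_sd Extra white observation noise s.d. added to the
#'   fluorescence series.
#' @param lag_frames Lead of fluorescence over movement, in frames.
#' @param seed Integer seed.
#' @return List with \code{fluorescence}, \code{movement},
#'   \code{truth} (coupling, lag, ar_coeff, seed).
#' @export
generate_coupled_series <- function(n_points, coupling = 0,
                                    ar_coeff = 0.6, noise_sd = 0,
                                    lag_frames = 0L, seed = 1L) {
  if (n_points < 17) stop("'n_points' must be >= 17", call. = FALSE)
  if (abs(ar_coeff) >= 1) stop("|ar_coeff| must be < 1", call. = FALSE)
  if (coupling < 0 || coupling > 1) {
    stop("'coupling' must be in [0, 1]", call. = FALSE)
  }
  set.seed(seed)
  lag <- as.integer(lag_frames)
  n_ext <- n_points + abs(lag)
  m_ext <- ar1_series(n_ext, ar_coeff)
  z <- ar1_series(n_points, ar_coeff)
  m <- if (lag >= 0) m_ext[seq_len(n_points)] else
    m_ext[(abs(lag) + 1):n_ext]
  m_lead <- if (lag >= 0) m_ext[(lag + 1):(lag + n_points)] else
    m_ext[seq_len(n_points)]
  f <- coupling * m_lead + sqrt(1 - coupling^2) * z
  if (noise_sd > 0) f <- f + rnorm(n_points, 0, noise_sd)
  list(fluorescence = f, movement = m,
       truth = list(coupling = coupling, lag_frames = lag,
                    ar_coeff = ar_coeff, seed = seed))
}
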