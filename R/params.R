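#' Segmentation parameters
#'
#' Parameter container for frame segmentation. Defaults follow the
#' reference growth-cone workflow: LoG scale \code{sigma_log = 2.6} px,
#' Renyi-entropy auto-thresholding, 4 erode/dilate iterations, 65 nm
#' pixels and 2 s frame interval.
#'
#' @param sigma_log LoG scale sigma in pixels (> 0).
#' @param threshold_method Name of an auto-threshold algorithm; see
#'   \code{\link{threshold_methods}}.
#' @param adaptive Logical; use the 8-directional adaptive LoG variant.
#' @param ed_iterations Number of erode steps (then the same number of
#'   dilate steps) used to delete thin protrusions from the mask (>= 1).
#' @param join_fragments Logical; reconnect detached protrusion
#'   fragments to the cell body.
#' @param base_back_frames Number of pre-formation frames over which the
#'   base position is back-predicted (>= 0).
#' @param pixel_size_nm Pixel width in nanometres (> 0).
#' @param frame_interval_s Frame interval in seconds (> 0).
#' @param element Structuring element for erosion/dilation: "box"
#'   (3x3 square, 8-connected; default) or "disc" (diamond).
#' @param min_protrusion_px Minimum pixel count for a mask-minus-body
#'   component to count as a protrusion; smaller residues (opening
#'   artifacts on curved boundaries) are merged back into the body.
#' @return An object of class \code{segmentation_params}.
#' @export
segmentation_params <- function(sigma_log = 2.6,
                                threshold_method = "RenyiEntropy",
                                adaptive = FALSE,
                                ed_iterations = 4L,
                                join_fragments = FALSE,
                                base_back_frames = 20L,
                                pixel_size_nm = 65,
                                frame_interval_s = 2,
                                element = c("box", "disc"),
                                min_protrusion_px = 9L) {
  element <- match.arg(element)
  stopifnot(is.numeric(sigma_log), length(sigma_log) == 1L)
  if (sigma_log <= 0) stop("'sigma_log' must be > 0", call. = FALSE)
  if (ed_iterations < 1) stop("'ed_iterations' must be >= 1", call. = FALSE)
  if (base_back_frames < 0) stop("'base_back_frames' must be >= 0", call. = FALSE)
  if (pixel_size_nm <= 0) stop("'pixel_size_nm' must be > 0", call. = FALSE)
  if (frame_interval_s <= 0) stop("'frame_interval_s' must be > 0", call. = FALSE)
  match_threshold_method(threshold_method)
  structure(list(sigma_log = sigma_log,
                 threshold_method = threshold_method,
                 adaptive = isTRUE(adaptive),
                 ed_iterations = as.integer(ed_iterations),
                 join_fragments = isTRUE(join_fragments),
                 base_back_frames = as.integer(base_back_frames),
                 pixel_size_nm = pixel_size_nm,
                 frame_interval_s = frame_interval_s,
                 element = element,
                 min_protrusion_px = as.integer(min_protrusion_px)),
            class = "segmentation_params")
}

#' Track filtering thresholds
#'
#' Defaults are the reference thresholds for growth-cone filopodia:
#' at least 3 frames, maximum length at least 1.8 um, at least one
#' frame-to-frame length change of 0.1 um, mean waviness at most 0.35.
#'
#' @param min_frames Minimum number of frames a track must span.
#' @param min_start_frame Minimum first frame index (1-based); 2 keeps
#'   only filopodia whose formation is observed.
#' @param min_max_length_um Minimum of the track's maximum corrected
#'   length, in micrometres.
#' @param min_length_change_um Minimum of the track's maximum absolute
#'   frame-to-frame length change, in micrometres.
#' @param max_mean_waviness Maximum mean waviness (1 - straightness).
#' @return An object of class \code{track_filter_params}.
#' @export
track_filter_params <- function(min_frames = 3L,
                                min_start_frame = 1L,
                                min_max_length_um = 1.8,
                                min_length_change_um = 0.1,
                                max_mean_waviness = 0.35) {
  stopifnot(min_frames >= 0, min_start_frame >= 0,
            min_max_length_um >= 0, min_length_change_um >= 0,
            max_mean_waviness >= 0, max_mean_waviness <= 1)
  structure(list(min_frames = as.integer(min_frames),
                 min_start_frame = as.integer(min_start_frame),
                 min_max_length_um = min_max_length_um,
                 min_length_change_um = min_length_change_um,
                 max_mean_waviness = max_mean_waviness),
            class = "track_filter_params")
}

#' Time-series and state-classification parameters
#'
#' Houses the constants of the downstream analysis: the +/-32.5 nm/s
#' extension/retraction threshold over a 10 s window, the five-step
#' rolling mean, the 0.5-99.5 percentile outlier filter, the
#' new-filopodium gate (starting length < 2 um), the 10-point initial
#' window, the 3-point pre-formation summary, and the 17-point minimum
#' for cross-correlation analysis.
#'
#' @param state_threshold_nm_s Speed threshold separating extension /
#'   stalling / retraction, in nm/s.
#' @param state_window_s Window over which movement must be consistent
#'   to assign a state, in seconds.
#' @param rolling_window Width of the centered rolling mean, in steps.
#' @param percentile_low,percentile_high Percentile bounds (in percent)
#'   of the outlier rejection filter.
#' @param new_filo_max_start_length_um Maximum starting length for a
#'   track to count as a newly formed filopodium, in micrometres.
#' @param initial_window_points Number of leading time points used for
#'   the initial tip/base movement summaries.
#' @param preformation_points Number of pre-formation time points
#'   averaged into the pre-formation fluorescence summary.
#' @param min_series_points_ccf Minimum paired time points required for
#'   cross-correlation analysis.
#' @return An object of class \code{analysis_params}.
#' @export
analysis_params <- function(state_threshold_nm_s = 32.5,
                            state_window_s = 10,
                            rolling_window = 5L,
                            percentile_low = 0.5,
                            percentile_high = 99.5,
                            new_filo_max_start_length_um = 2,
                            initial_window_points = 10L,
                            preformation_points = 3L,
                            min_series_points_ccf = 17L) {
  stopifnot(state_threshold_nm_s > 0, state_window_s > 0,
            rolling_window >= 1, rolling_window %% 2 == 1,
            percentile_low >= 0, percentile_high <= 100,
            percentile_low < percentile_high)
  structure(list(state_threshold_nm_s = state_threshold_nm_s,
                 state_window_s = state_window_s,
                 rolling_window = as.integer(rolling_window),
                 percentile_low = percentile_low,
                 percentile_high = percentile_high,
                 new_filo_max_start_length_um = new_filo_max_start_length_um,
                 initial_window_points = as.integer(initial_window_points),
                 preformation_points = as.integer(preformation_points),
                 min_series_points_ccf = as.integer(min_series_points_ccf)),
            class = "analysis_params")
}

#' Convert a per-frame pixel displacement to a speed in nm/s
#'
#' One pixel per frame at 65 nm pixels and 2 s frames is 32.5 nm/s --
#' the canonical extension/retraction state threshold.
#'
#' @param px_per_frame Displacement in pixels per frame.
#' @param pixel_size_nm Pixel width in nm.
#' @param frame_interval_s Frame interval in seconds.
#' @return Speed in nm/s.
#' @examples
#' px_per_frame_to_nm_s(1, 65, 2)  # 32.5
#' @export
px_per_frame_to_nm_s <- function(px_per_frame, pixel_size_nm, frame_interval_s) {
  stopifnot(pixel_size_nm > 0, frame_interval_s > 0)
  px_per_frame * pixel_size_nm / frame_interval_s
}

#' Full width at half maximum of the LoG scale
#'
#' Estimated filopodium width \code{w = 2 sqrt(2 ln 2) sigma px},
#' the FWHM of a Gaussian of scale \code{sigma} (in pixels) at pixel
#' width \code{px} nm.
#'
#' @param sigma_log LoG sigma in pixels.
#' @param pixel_size_nm Pixel width in nm.
#' @return Width in nm.
#' @examples
#' fwhm_width_nm(2.6, 65)  # ~398 nm
#' @export
fwhm_width_nm <- function(sigma_log, pixel_size_nm) {
  2 * sqrt(2 * log(2)) * sigma_log * pixel_size_nm
}
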