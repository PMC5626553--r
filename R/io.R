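#' Read a multi-page TIFF time-lapse
#'
#' Reads a grayscale multi-page TIFF into a normalized in-memory
#' representation. Pages are interpreted as T frames of
#' \code{n_channels} interleaved channels (channel fastest); a
#' single-channel stack is simply T pages. Calibration comes from the
#' arguments (the caller's config), not from TIFF metadata.
#'
#' @param path TIFF file path.
#' @param n_channels Number of interleaved channels.
#' @param mapping_channel Index of the membrane-marker channel used
#'   for segmentation.
#' @param measurement_channel Index of the quantified channel, or NA.
#' @param pixel_size_nm,frame_interval_s Calibration (required).
#' @return A \code{timelapse}: list with \code{frames} (frames[[t]][[c]]
#'   is a numeric matrix), \code{n_frames}, \code{n_channels}, channel
#'   roles and calibration.
#' @export
read_timelapse <- function(path, n_channels = 1L, mapping_channel = 1L,
                           measurement_channel = NA_integer_,
                           pixel_size_nm = NULL, frame_interval_s = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (is.null(pixel_size_nm) || is.null(frame_interval_s)) {
    stop("calibration required: give 'pixel_size_nm' and 'frame_interval_s'",
         call. = FALSE)
  }
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) %% n_channels != 0) {
    stop("page count ", length(pages), " not divisible by n_channels = ",
         n_channels, "; give the correct channel count", call. = FALSE)
  }
  for (ch in c(mapping_channel, measurement_channel)) {
    if (!is.na(ch) && (ch < 1 || ch > n_channels)) {
      stop("channel index ", ch, " out of range; available channels: 1..",
           n_channels, call. = FALSE)
    }
  }
  n_frames <- length(pages) %/% n_channels
  frames <- lapply(seq_len(n_frames), function(t)
    lapply(seq_len(n_channels), function(c)
      matrix(as.numeric(pages[[(t - 1L) * n_channels + c]]),
             nrow(pages[[1]]), ncol(pages[[1]]))))
  structure(list(frames = frames, n_frames = n_frames,
                 n_channels = as.integer(n_channels),
                 mapping_channel = as.integer(mapping_channel),
                 measurement_channel = as.integer(measurement_channel),
                 pixel_size_nm = pixel_size_nm,
                 frame_interval_s = frame_interval_s),
            class = "timelapse")
}

#' Write matrices as a 16-bit multi-page TIFF
#'
#' Integer intensities (camera counts, 0..65535) survive a write/read
#' round trip exactly.
#'
#' @param pages List of numeric matrices (interleave channels
#'   yourself for multi-channel stacks).
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_timelapse <- function(pages, path) {
  tiff::writeTIFF(lapply(pages, function(m) {
    storage.mode(m) <- "double"
    m / 65535
  }), path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}

#' Convert a generated movie to a timelapse object
#'
#' @param movie Result of \code{\link{generate_movie}}.
#' @return A \code{timelapse} with channel 1 = mapping, channel 2 =
#'   measurement.
#' @export
as_timelapse <- function(movie) {
  spec <- movie$spec
  frames <- lapply(seq_len(spec$n_frames), function(t)
    list(movie$mapping[[t]], movie$measurement[[t]]))
  structure(list(frames = frames, n_frames = spec$n_frames,
                 n_channels = 2L, mapping_channel = 1L,
                 measurement_channel = 2L,
                 pixel_size_nm = spec$pixel_size_nm,
                 frame_interval_s = spec$frame_interval_s),
            class = "timelapse")
}

#' Write a table with a units header
#'
#' CSV preceded by '#'-prefixed comment lines declaring the units of
#' each column; read back with \code{\link{read_units_csv}}.
#'
#' @param df Data frame.
#' @param path Output path.
#' @param units Character string describing units.
#' @return The path, invisibly.
#' @export
write_units_csv <- function(df, path, units = "") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", units), con)
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_units_csv
#' @export
read_units_csv <- function(path) {
  read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Pipeline configuration
#'
#' Bundles segmentation, tracking, filtering and analysis parameters
#' with channel roles, seed and output directory; round-trips
#' losslessly through YAML.
#'
#' @param input Path to a TIFF stack (or NA when a timelapse is passed
#'   to \code{\link{run_pipeline}} directly).
#' @param output_dir Output directory.
#' @param n_channels,mapping_channel,measurement_channel Channel
#'   layout.
#' @param pixel_size_nm,frame_interval_s Calibration.
#' @param segmentation,filtering,analysis,tracking Parameter objects
#'   (defaults used when NULL).
#' @param tip_fitting Logical; refine tips against the measurement
#'   channel.
#' @param edits_file Optional CSV of track edits to replay.
#' @param seed Integer seed for all stochastic stages.
#' @param log_level "info" or "quiet".
#' @return An object of class \code{pipeline_config}.
#' @export
pipeline_config <- function(input = NA_character_, output_dir = tempfile("filotrack_"),
                            n_channels = 1L, mapping_channel = 1L,
                            measurement_channel = NA_integer_,
                            pixel_size_nm = 65, frame_interval_s = 2,
                            segmentation = NULL, filtering = NULL,
                            analysis = NULL, tracking = NULL,
                            tip_fitting = FALSE, edits_file = NA_character_,
                            seed = 1L, log_level = "info") {
  if (is.null(segmentation)) {
    segmentation <- segmentation_params(pixel_size_nm = pixel_size_nm,
                                        frame_interval_s = frame_interval_s)
  }
  if (is.null(filtering)) filtering <- track_filter_params()
  if (is.null(analysis)) analysis <- analysis_params()
  if (is.null(tracking)) tracking <- tracking_params()
  structure(list(input = input, output_dir = output_dir,
                 n_channels = as.integer(n_channels),
                 mapping_channel = as.integer(mapping_channel),
                 measurement_channel = as.integer(measurement_channel),
                 pixel_size_nm = pixel_size_nm,
                 frame_interval_s = frame_interval_s,
                 segmentation = segmentation, filtering = filtering,
                 analysis = analysis, tracking = tracking,
                 tip_fitting = isTRUE(tip_fitting),
                 edits_file = edits_file, seed = as.integer(seed),
                 log_level = log_level),
            class = "pipeline_config")
}

#' Read / write a pipeline configuration as YAML
#'
#' @param config A \code{\link{pipeline_config}}.
#' @param path YAML file path.
#' @return \code{read_config} returns the \code{pipeline_config}.
#' @export
write_config <- function(config, path) {
  plain <- unclass(config)
  for (f in c("segmentation", "filtering", "analysis", "tracking")) {
    plain[[f]] <- unclass(plain[[f]])
  }
  plain$tracking$max_cost <- ifelse(is.finite(plain$tracking$max_cost),
                                    plain$tracking$max_cost, ".inf")
  yaml::write_yaml(plain, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (identical(y$tracking$max_cost, ".inf")) y$tracking$max_cost <- Inf
  pipeline_config(
    input = y$input, output_dir = y$output_dir,
    n_channels = y$n_channels, mapping_channel = y$mapping_channel,
    measurement_channel = ifelse(is.null(y$measurement_channel) ||
                                   is.na(y$measurement_channel),
                                 NA_integer_, y$measurement_channel),
    pixel_size_nm = y$pixel_size_nm,
    frame_interval_s = y$frame_interval_s,
    segmentation = do.call(segmentation_params, y$segmentation),
    filtering = do.call(track_filter_params, y$filtering),
    analysis = do.call(analysis_params, y$analysis),
    tracking = do.call(tracking_params, y$tracking),
    tip_fitting = y$tip_fitting,
    edits_file = ifelse(is.null(y$edits_file) || is.na(y$edits_file),
                        NA_character_, y$edits_file),
    seed = y$seed, log_level = y$log_level)
}
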