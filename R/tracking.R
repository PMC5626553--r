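#' Tracking parameters
#'
#' @param max_cost Maximum admissible link cost; candidate links above
#'   it are rejected (default Inf: only zero-overlap pairs are
#'   forbidden).
#' @param max_gap Maximum frame gap closed when re-linking a track that
#'   skipped frames (0 = one-step linking only).
#' @param no_link_quantile Quantile of the finite candidate costs used
#'   as the birth/death (no-link) cost.
#' @return An object of class \code{tracking_params}.
#' @export
tracking_params <- function(max_cost = Inf, max_gap = 0L,
                            no_link_quantile = 0.95) {
  stopifnot(max_cost > 0, max_gap >= 0,
            no_link_quantile > 0, no_link_quantile <= 1)
  structure(list(max_cost = max_cost, max_gap = as.integer(max_gap),
                 no_link_quantile = no_link_quantile),
            class = "tracking_params")
}

#' Link cost between two protrusions
#'
#' \deqn{cost = \frac{dist(base_1, base_2) + dist(tip_1, tip_2)}
#'   {\mathrm{overlap\ area}} \, \delta T}
#' Distances are in pixels, overlap is the shared pixel count of the
#' two protrusion masks, and \eqn{\delta T} the frame gap in frames.
#' Zero overlap makes the link inadmissible (cost Inf).
#'
#' @param geom1,geom2 \code{protrusion_geometry} objects.
#' @param pixels1,pixels2 Integer vectors of linear pixel indices of
#'   the two protrusion masks.
#' @param dT Frame gap (>= 1).
#' @return Non-negative cost (Inf when masks do not overlap).
#' @export
link_cost <- function(geom1, geom2, pixels1, pixels2, dT = 1) {
  overlap <- length(intersect(pixels1, pixels2))
  if (overlap == 0) return(Inf)
  d_base <- sqrt(sum((geom1$base_xy - geom2$base_xy)^2))
  d_tip <- sqrt(sum((geom1$tip_xy - geom2$tip_xy)^2))
  (d_base + d_tip) / overlap * dT
}

#' Minimal-cost one-to-one assignment
#'
#' Solves the linear assignment problem for a square (or wide)
#' non-negative cost matrix, returning for each row the assigned
#' column. The solution minimizes the total cost.
#'
#' @param cost Numeric matrix, \code{nrow(cost) <= ncol(cost)}, finite
#'   non-negative entries.
#' @return Integer vector of assigned columns, one per row.
#' @export
solve_assignment <- function(cost) {
  stopifnot(is.matrix(cost), all(is.finite(cost)), all(cost >= 0),
            nrow(cost) <= ncol(cost))
  as.integer(clue::solve_LSAP(cost))
}

#' One-step Hungarian linking of two frames
#'
#' Builds the full cost matrix between the previous and next frame's
#' protrusions and solves the linear assignment problem, with
#' birth/death handled by padding the matrix with a no-link cost (a
#' configurable quantile of the finite candidate costs). Links whose
#' cost exceeds \code{max_cost} or whose masks do not overlap are
#' rejected: the previous protrusion ends and the next one starts a
#' new track.
#'
#' @param prev,nxt Lists of entries, each a list with \code{geom} and
#'   \code{pixels}; either may be empty.
#' @param dT Frame gap in frames (scalar, or one value per prev entry).
#' @param params A \code{\link{tracking_params}}.
#' @return List with \code{links} (data frame prev, nxt, cost),
#'   \code{deaths} (indices into prev), \code{births} (indices into
#'   nxt).
#' @export
link_frames <- function(prev, nxt, dT = 1, params = tracking_params()) {
  n <- length(prev); m <- length(nxt)
  if (n == 0 || m == 0) {
    return(list(links = data.frame(prev = integer(0), nxt = integer(0),
                                   cost = numeric(0)),
                deaths = seq_len(n), births = seq_len(m)))
  }
  dT <- rep_len(dT, n)
  C <- matrix(Inf, n, m)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    C[i, j] <- link_cost(prev[[i]]$geom, nxt[[j]]$geom,
                         prev[[i]]$pixels, nxt[[j]]$pixels, dT[i])
  }
  finite <- C[is.finite(C)]
  no_link <- if (length(finite)) {
    max(quantile(finite, params$no_link_quantile, names = FALSE), 1e-9)
  } else 1
  if (is.finite(params$max_cost)) no_link <- min(no_link, params$max_cost)
  big <- (no_link + if (length(finite)) max(finite) else 0 + 1) * (n + m) * 10
  M <- matrix(big, n + m, n + m)
  M[seq_len(n), seq_len(m)] <- ifelse(is.finite(C), C, big)
  for (i in seq_len(n)) M[i, m + i] <- no_link            # death of prev i
  for (j in seq_len(m)) M[n + j, j] <- no_link            # birth of nxt j
  M[(n + 1):(n + m), (m + 1):(m + n)] <- 0                # dummy-dummy
  sol <- solve_assignment(M)
  links <- data.frame(prev = integer(0), nxt = integer(0), cost = numeric(0))
  for (i in seq_len(n)) {
    j <- sol[i]
    if (j <= m && is.finite(C[i, j]) && C[i, j] <= params$max_cost &&
        C[i, j] < big) {
      links <- rbind(links, data.frame(prev = i, nxt = j, cost = C[i, j]))
    }
  }
  list(links = links,
       deaths = setdiff(seq_len(n), links$prev),
       births = setdiff(seq_len(m), links$nxt))
}

#' Build filopodium tracks across a movie
#'
#' Applies \code{\link{link_frames}} frame by frame. Every protrusion
#' belongs to exactly one track; unlinked protrusions start new
#' tracks. With \code{max_gap > 0}, tracks that missed up to that many
#' frames remain candidates for re-linking (the frame gap enters the
#' cost as \eqn{\delta T}).
#'
#' @param frames List over time; \code{frames[[t]]} is a list of
#'   entries with \code{geom} and \code{pixels} (as produced by
#'   \code{\link{frame_protrusions}}).
#' @param params A \code{\link{tracking_params}}.
#' @return List of tracks, each a list with \code{track_id},
#'   \code{frames} (integer vector), \code{geoms}, \code{pixels};
#'   ordered by first frame then by label.
#' @export
build_tracks <- function(frames, params = tracking_params()) {
  stopifnot(length(frames) >= 1)
  tracks <- list()     # each: frames, geoms, pixels, last_frame, open
  for (t in seq_along(frames)) {
    cur <- frames[[t]]
    open_idx <- which(vapply(tracks, function(tr)
      tr$open && (t - tr$last_frame) <= 1L + params$max_gap, TRUE))
    prev <- lapply(open_idx, function(i) {
      tr <- tracks[[i]]
      k <- length(tr$frames)
      list(geom = tr$geoms[[k]], pixels = tr$pixels[[k]])
    })
    dT <- vapply(open_idx, function(i) t - tracks[[i]]$last_frame, 0L)
    asg <- link_frames(prev, cur, dT, params)
    linked_next <- integer(0)
    if (nrow(asg$links)) {
      for (r in seq_len(nrow(asg$links))) {
        ti <- open_idx[asg$links$prev[r]]
        j <- asg$links$nxt[r]
        tracks[[ti]]$frames <- c(tracks[[ti]]$frames, t)
        tracks[[ti]]$geoms <- c(tracks[[ti]]$geoms, list(cur[[j]]$geom))
        tracks[[ti]]$pixels <- c(tracks[[ti]]$pixels, list(cur[[j]]$pixels))
        tracks[[ti]]$last_frame <- t
        linked_next <- c(linked_next, j)
      }
    }
    if (params$max_gap == 0L) {
      for (i in open_idx[asg$deaths]) tracks[[i]]$open <- FALSE
    }
    for (j in setdiff(seq_along(cur), linked_next)) {
      tracks[[length(tracks) + 1L]] <- list(
        frames = t, geoms = list(cur[[j]]$geom),
        pixels = list(cur[[j]]$pixels), last_frame = t, open = TRUE)
    }
  }
  tracks <- lapply(seq_along(tracks), function(i) {
    tr <- tracks[[i]]
    list(track_id = i, frames = tr$frames, geoms = tr$geoms,
         pixels = tr$pixels)
  })
  tracks
}

#' Extract linkable protrusion entries from a frame segmentation
#'
#' @param seg A \code{frame_segmentation}.
#' @param params A \code{\link{segmentation_params}}.
#' @param measurement_image,tip_fitting Passed to
#'   \code{\link{frame_geometries}}.
#' @return List of entries with \code{geom} and \code{pixels}.
#' @export
frame_protrusions <- function(seg, params = segmentation_params(),
                              measurement_image = NULL,
                              tip_fitting = FALSE) {
  geoms <- frame_geometries(seg, params, measurement_image, tip_fitting)
  lapply(geoms, function(g)
    list(geom = g, pixels = which(seg$protrusion_labels == g$label)))
}

#' Filter tracks on duration, start, length and waviness
#'
#' Retains tracks with at least \code{min_frames} frames, first frame
#' at or after \code{min_start_frame}, maximum corrected length of at
#' least \code{min_max_length_um}, at least one frame-to-frame length
#' change of magnitude \code{min_length_change_um}, and mean waviness
#' at most \code{max_mean_waviness}. A pure filter: the output is an
#' order-preserving subset of the input.
#'
#' @param tracks List of tracks.
#' @param fparams A \code{\link{track_filter_params}}.
#' @param params A \code{\link{segmentation_params}} (for lengths).
#' @return Filtered list of tracks.
#' @export
filter_tracks <- function(tracks, fparams = track_filter_params(),
                          params = segmentation_params()) {
  keep <- vapply(tracks, function(tr) {
    if (length(tr$frames) < fparams$min_frames) return(FALSE)
    if (tr$frames[1] < fparams$min_start_frame) return(FALSE)
    len <- vapply(tr$geoms, corrected_length, 0, params = params)
    if (all(is.na(len))) return(FALSE)
    if (max(len, na.rm = TRUE) < fparams$min_max_length_um) return(FALSE)
    if (fparams$min_length_change_um > 0) {
      dl <- abs(diff(len))
      dl[diff(tr$frames) != 1L] <- NA
      if (!any(dl >= fparams$min_length_change_um, na.rm = TRUE)) return(FALSE)
    }
    if (fparams$max_mean_waviness < 1) {
      wav <- vapply(seq_along(len), function(i)
        straightness(tr$geoms[[i]], len[i], params)$waviness, 0)
      if (mean(wav, na.rm = TRUE) > fparams$max_mean_waviness) return(FALSE)
    }
    TRUE
  }, TRUE)
  tracks[keep]
}

#' Apply programmatic track edits
#'
#' Supported operations (a programmatic stand-in for interactive
#' error correction):
#' \describe{
#'   \item{delete}{remove a whole track}
#'   \item{delete_range}{remove frames \code{frame_from..frame_to}
#'     from a track (an emptied track is removed)}
#'   \item{relink}{append the frames of track \code{target_id} after
#'     frame \code{frame_from} to the end of \code{track_id} and
#'     remove \code{target_id}}
#' }
#' Each applied edit is recorded in the \code{edit_log} attribute of
#' the returned list. Edits referencing unknown tracks or frames fail
#' with an error naming the offending edit, so re-applying an already
#' applied edit (e.g. deleting a deleted track) is rejected.
#'
#' @param tracks List of tracks.
#' @param edits Data frame with columns \code{op}, \code{track_id},
#'   \code{frame_from}, \code{frame_to}, \code{target_id}.
#' @return Edited list of tracks with an \code{edit_log} attribute.
#' @export
edit_tracks <- function(tracks, edits) {
  ids <- vapply(tracks, `[[`, 0L, "track_id")
  log <- attr(tracks, "edit_log")
  if (is.null(log)) log <- edits[0, , drop = FALSE]
  for (r in seq_len(nrow(edits))) {
    e <- edits[r, ]
    i <- match(e$track_id, ids)
    if (is.na(i)) {
      stop("edit ", r, " (", e$op, "): no track with id ", e$track_id,
           call. = FALSE)
    }
    if (e$op == "delete") {
      tracks[[i]] <- NULL
      ids <- ids[-i]
    } else if (e$op == "delete_range") {
      tr <- tracks[[i]]
      drop <- tr$frames >= e$frame_from & tr$frames <= e$frame_to
      if (!any(drop)) {
        stop("edit ", r, " (delete_range): track ", e$track_id,
             " has no frames in ", e$frame_from, "..", e$frame_to,
             call. = FALSE)
      }
      if (all(drop)) {
        tracks[[i]] <- NULL
        ids <- ids[-i]
      } else {
        tr$frames <- tr$frames[!drop]
        tr$geoms <- tr$geoms[!drop]
        tr$pixels <- tr$pixels[!drop]
        tracks[[i]] <- tr
      }
    } else if (e$op == "relink") {
      j <- match(e$target_id, ids)
      if (is.na(j)) {
        stop("edit ", r, " (relink): no track with id ", e$target_id,
             call. = FALSE)
      }
      a <- tracks[[i]]; b <- tracks[[j]]
      keep_a <- a$frames <= e$frame_from
      keep_b <- b$frames > e$frame_from
      if (!any(keep_b)) {
        stop("edit ", r, " (relink): target track ", e$target_id,
             " has no frames after ", e$frame_from, call. = FALSE)
      }
      a$frames <- c(a$frames[keep_a], b$frames[keep_b])
      a$geoms <- c(a$geoms[keep_a], b$geoms[keep_b])
      a$pixels <- c(a$pixels[keep_a], b$pixels[keep_b])
      if (is.unsorted(a$frames, strictly = TRUE)) {
        stop("edit ", r, " (relink): frames of ", e$track_id, " and ",
             e$target_id, " overlap at/after frame ", e$frame_from,
             call. = FALSE)
      }
      tracks[[i]] <- a
      tracks[[j]] <- NULL
      ids <- vapply(tracks, `[[`, 0L, "track_id")
    } else {
      stop("edit ", r, ": unknown op '", e$op, "'", call. = FALSE)
    }
    log <- rbind(log, e)
  }
  attr(tracks, "edit_log") <- log
  tracks
}

#' Read / write an edits file
#'
#' Edits are stored as CSV with columns op, track_id, frame_from,
#' frame_to, target_id; replaying the file through
#' \code{\link{edit_tracks}} reproduces the edited tracks.
#'
#' @param edits Data frame of edits.
#' @param path File path.
#' @return \code{read_edits} returns the edits data frame.
#' @export
write_edits <- function(edits, path) {
  write.csv(edits, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_edits
#' @export
read_edits <- function(path) {
  e <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("op", "track_id", "frame_from", "frame_to", "target_id")
  missing <- setdiff(need, names(e))
  if (length(missing)) {
    stop("edits file lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  e
}

#' Long-format track table
#'
#' One row per (track, frame) with base/tip coordinates (x = column,
#' y = row, 1-based), area and perimeter.
#'
#' @param tracks List of tracks.
#' @return Data frame.
#' @export
tracks_to_table <- function(tracks) {
  rows <- lapply(tracks, function(tr) {
    data.frame(
      track_id = tr$track_id,
      frame = tr$frames,
      base_x = vapply(tr$geoms, function(g) g$base_xy[2], 0),
      base_y = vapply(tr$geoms, function(g) g$base_xy[1], 0),
      tip_x = vapply(tr$geoms, function(g) g$tip_xy[2], 0),
      tip_y = vapply(tr$geoms, function(g) g$tip_xy[1], 0),
      area_px = vapply(tr$geoms, `[[`, 0, "area_px"),
      perimeter_px = vapply(tr$geoms, `[[`, 0, "perimeter_px")
    )
  })
  do.call(rbind, rows)
}
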