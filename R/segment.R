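#' 8-connected labeling of a binary mask
#'
#' Labels connected components using 8-connectivity (edge or corner
#' adjacency). Labels are renumbered 1..k in raster order of each
#' component's first pixel, which makes ties and ordering
#' deterministic.
#'
#' @param mask Logical or 0/1 matrix.
#' @return Integer matrix of component labels (0 = background).
#' @export
label8 <- function(mask) {
  m <- (mask > 0) * 1
  lab <- EBImage::imageData(EBImage::bwlabel(m))
  dim(lab) <- dim(m)
  n <- max(lab)
  if (n <= 1L) return(matrix(as.integer(lab), nrow(m), ncol(m)))
  # merge 4-connected labels that touch diagonally (union-find)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  nr <- nrow(lab); nc <- ncol(lab)
  a <- lab[-nr, -nc]; b <- lab[-1, -1]    # NW-SE diagonal pairs
  c1 <- lab[-nr, -1]; d1 <- lab[-1, -nc]  # NE-SW diagonal pairs
  pairs <- rbind(cbind(as.vector(a), as.vector(b)),
                 cbind(as.vector(c1), as.vector(d1)))
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 & pairs[, 1] != pairs[, 2], ,
                 drop = FALSE]
  if (nrow(pairs)) {
    pairs <- unique(pairs)
    for (i in seq_len(nrow(pairs))) {
      r1 <- find(pairs[i, 1]); r2 <- find(pairs[i, 2])
      if (r1 != r2) parent[max(r1, r2)] <- min(r1, r2)
    }
  }
  root <- vapply(seq_len(n), find, 0L)
  out <- matrix(0L, nr, nc)
  out[lab > 0] <- root[lab[lab > 0]]
  # renumber by first occurrence in column-major scan order
  present <- sort(unique(out[out > 0]))
  renum <- integer(max(present))
  renum[present[order(match(present, as.vector(out)))]] <- seq_along(present)
  out[out > 0] <- renum[out[out > 0]]
  out
}

#' Keep the largest connected component
#'
#' The largest 8-connected object in the field of view is taken to be
#' the cell body / growth cone. Ties are broken deterministically in
#' favour of the component whose first pixel comes earliest in raster
#' order (the lowest label index).
#'
#' @param mask Logical matrix.
#' @return Logical matrix retaining only the largest component.
#' @export
extract_cell_mask <- function(mask) {
  if (!any(mask)) stop("no object: mask is empty", call. = FALSE)
  lab <- label8(mask)
  sizes <- tabulate(lab[lab > 0])
  keep <- which.max(sizes)  # lowest index on ties
  lab == keep
}

morph_brush <- function(element = "box") {
  if (element == "box") EBImage::makeBrush(3L, "box")
  else EBImage::makeBrush(3L, "diamond")
}

morph_n <- function(mask, op, n, element = "box") {
  br <- morph_brush(element)
  m <- mask * 1
  for (i in seq_len(n)) m <- op(m, br)
  md <- EBImage::imageData(m)
  dim(md) <- dim(mask)
  md > 0.5
}

#' Split a cell mask into body and protrusions
#'
#' Applies \code{n} binary erosions (enough to delete thin protrusions)
#' followed by \code{n} dilations to restore the body, then subtracts
#' the restored body from the original mask; the remaining 8-connected
#' components are the protrusions. Components that do not touch the
#' body are flagged as fragments (candidates for
#' \code{\link{join_fragments}}).
#'
#' @param mask Logical matrix: the cell mask (body plus protrusions).
#' @param ed_iterations Number of erode/dilate iterations (>= 1).
#' @param element Structuring element, "box" or "disc".
#' @param min_protrusion_px Components smaller than this are opening
#'   residues on curved boundaries, not protrusions; they rejoin the
#'   body.
#' @return A \code{frame_segmentation}: list with \code{body_mask},
#'   \code{protrusion_labels}, \code{boundary} (closed polygon of body
#'   boundary pixels, 1-based (row, col)), \code{fragment_labels},
#'   \code{mask}.
#' @export
split_body_protrusions <- function(mask, ed_iterations, element = "box",
                                   min_protrusion_px = 9L) {
  stopifnot(ed_iterations >= 1)
  er <- morph_n(mask, EBImage::erode, ed_iterations, element)
  if (!any(er)) {
    stop("over-erosion: ", ed_iterations,
         " erode steps removed the whole mask; use a smaller 'ed_iterations'",
         call. = FALSE)
  }
  body <- morph_n(er, EBImage::dilate, ed_iterations, element) & mask
  prot <- mask & !body
  labels <- label8(prot)
  if (max(labels) > 0 && min_protrusion_px > 1) {
    small <- which(tabulate(labels[labels > 0]) < min_protrusion_px)
    if (length(small)) {
      body <- body | (matrix(labels %in% small, nrow(labels)) & mask)
      labels <- label8(mask & !body)
    }
  }
  frag <- setdiff(seq_len(max(labels)),
                  unique(labels[touching_mask(labels, body)]))
  structure(list(body_mask = body,
                 protrusion_labels = labels,
                 boundary = trace_boundary(body),
                 fragment_labels = as.integer(frag),
                 mask = mask),
            class = "frame_segmentation")
}

# TRUE where a labeled pixel has an 8-neighbour inside `target`
touching_mask <- function(labels, target) {
  grown <- morph_n(target, EBImage::dilate, 1L, "box")
  labels > 0 & grown
}

#' @export
print.frame_segmentation <- function(x, ...) {
  cat("frame_segmentation:", sum(x$body_mask), "body px,",
      max(x$protrusion_labels), "protrusions",
      if (length(x$fragment_labels))
        paste0("(", length(x$fragment_labels), " fragment(s))") else "",
      "\n")
  invisible(x)
}

# Ordered closed boundary polygon of the largest component, 1-based.
trace_boundary <- function(mask) {
  oc <- EBImage::ocontour(mask * 1)
  if (!length(oc)) return(matrix(numeric(0), 0, 2))
  best <- which.max(vapply(oc, nrow, 0L))
  b <- oc[[best]] + 1
  colnames(b) <- c("row", "col")
  b
}

# Chain-code perimeter of an 8-connected contour with the
# Vossepoel-Smeulders correction: 0.980 per axial step, 1.406 per
# diagonal step, -0.091 per direction change. This removes most of the
# staircase bias of raw chain length on digitized smooth shapes.
chain_perimeter <- function(contour) {
  n <- nrow(contour)
  if (n < 2) return(4)  # isolated pixel: unit square
  steps <- diff(rbind(contour, contour[1, , drop = FALSE]))
  diag <- rowSums(abs(steps)) == 2
  corners <- sum(steps[, 1] != c(steps[-1, 1], steps[1, 1]) |
                   steps[, 2] != c(steps[-1, 2], steps[1, 2]))
  0.980 * sum(!diag) + 1.406 * sum(diag) - 0.091 * corners
}

#' Reconnect detached protrusion fragments
#'
#' Fragments (mask components not touching the cell body) are joined by
#' drawing the shortest 1-px line between the two closest pixels of a
#' fragment and its nearest neighbouring component; nearby fragments
#' therefore join each other first and the joined structure then
#' connects to the body. The procedure iterates until everything is
#' connected or a maximum of 10 iterations, after which any remaining
#' fragments stay flagged and are excluded from geometry.
#'
#' @param seg A \code{frame_segmentation}.
#' @param max_iter Maximum joining iterations.
#' @return An updated \code{frame_segmentation}.
#' @export
join_fragments <- function(seg, max_iter = 10L) {
  if (!length(seg$fragment_labels)) return(seg)
  full <- seg$mask | seg$body_mask
  for (iter in seq_len(max_iter)) {
    lab <- label8(full)
    main <- lab[which(seg$body_mask)[1]]
    ids <- setdiff(sort(unique(lab[lab > 0])), main)
    if (!length(ids)) break
    for (id in ids) {
      pix <- which(lab == id, arr.ind = TRUE)
      if (!nrow(pix)) next  # merged into another component this pass
      other <- which(lab > 0 & lab != id, arr.ind = TRUE)
      if (!nrow(other)) next
      d2 <- outer(pix[, 1], other[, 1], `-`)^2 +
        outer(pix[, 2], other[, 2], `-`)^2
      hit <- arrayInd(which.min(d2), dim(d2))
      line <- bresenham(pix[hit[1], ], other[hit[2], ])
      full[line] <- TRUE
    }
  }
  prot <- full & !seg$body_mask
  labels <- label8(prot)
  frag <- setdiff(seq_len(max(labels)),
                  unique(labels[touching_mask(labels, seg$body_mask)]))
  seg$protrusion_labels <- labels
  seg$fragment_labels <- as.integer(frag)
  seg$mask <- full
  seg
}

# 1-px-wide digital line between two (row, col) points, inclusive.
bresenham <- function(p0, p1) {
  dr <- p1[1] - p0[1]; dc <- p1[2] - p0[2]
  n <- max(abs(dr), abs(dc))
  if (n == 0) return(matrix(p0, 1, 2))
  t <- seq(0, 1, length.out = n + 1)
  cbind(round(p0[1] + t * dr), round(p0[2] + t * dc))
}

#' Base and tip geometry of one protrusion
#'
#' The base is the centroid of the pixels where the protrusion touches
#' the cell body, snapped to the nearest body-boundary pixel; the tip
#' is the protrusion pixel with maximum Euclidean distance from the
#' base. For bent or looping shapes the Euclidean-farthest rule can
#' misplace the tip; such shapes are outside the intended use.
#'
#' @param seg A \code{frame_segmentation}.
#' @param label Protrusion label.
#' @param params A \code{\link{segmentation_params}} (for sigma and
#'   calibration, used for the width and default tip radius).
#' @return A \code{protrusion_geometry}: list with \code{label},
#'   \code{area_px}, \code{perimeter_px}, \code{base_xy},
#'   \code{tip_xy} (1-based (row, col)), \code{tip_radius_px},
#'   \code{euclidean_D}, \code{width_w_px}, \code{flagged}.
#' @export
assign_base_tip <- function(seg, label, params = segmentation_params()) {
  labmat <- seg$protrusion_labels
  if (!any(labmat == label)) {
    stop("no protrusion with label ", label, call. = FALSE)
  }
  w_px <- 2 * sqrt(2 * log(2)) * params$sigma_log
  pix <- which(labmat == label, arr.ind = TRUE)
  if (label %in% seg$fragment_labels) {
    return(structure(list(label = label, area_px = nrow(pix),
                          perimeter_px = NA_real_, base_xy = c(NA, NA),
                          tip_xy = c(NA, NA), tip_radius_px = w_px / 2,
                          euclidean_D = NA_real_, width_w_px = w_px,
                          flagged = TRUE),
                     class = "protrusion_geometry"))
  }
  contact <- pix[touching_mask(labmat == label, seg$body_mask)[pix], ,
                 drop = FALSE]
  centroid <- colMeans(contact)
  bd <- seg$boundary
  d2 <- (bd[, 1] - centroid[1])^2 + (bd[, 2] - centroid[2])^2
  base <- as.numeric(bd[which.min(d2), ])
  dist2 <- (pix[, 1] - base[1])^2 + (pix[, 2] - base[2])^2
  tip <- as.numeric(pix[which.max(dist2), ])
  per <- chain_perimeter(trace_boundary(labmat == label))
  structure(list(label = label,
                 area_px = nrow(pix),
                 perimeter_px = per,
                 base_xy = base,
                 tip_xy = tip,
                 tip_radius_px = w_px / 2,
                 euclidean_D = sqrt(max(dist2)),
                 width_w_px = w_px,
                 flagged = FALSE),
            class = "protrusion_geometry")
}

#' Refine the tip position against the measurement channel
#'
#' Searches for strict local intensity maxima of the measurement image
#' within radius \code{r = sqrt((area/2)/pi)} (clamped to 3..20 px) of
#' the mapped tip. The tip moves to the intensity-weighted mean of the
#' maxima coordinates, and the tip radius becomes MSE/2, where MSE is
#' the mean squared distance of the maxima about the new tip. With no
#' maxima in range (e.g. a flat channel) the tip is left unchanged.
#'
#' @param geom A \code{protrusion_geometry}.
#' @param measurement_image Numeric matrix.
#' @param min_radius,max_radius Clamp bounds for the search radius, px.
#' @return Updated \code{protrusion_geometry}.
#' @export
fit_tip <- function(geom, measurement_image, min_radius = 3, max_radius = 20) {
  if (geom$flagged) return(geom)
  r <- min(max(sqrt((geom$area_px / 2) / pi), min_radius), max_radius)
  img <- measurement_image
  nr <- nrow(img); nc <- ncol(img)
  rows <- max(1, floor(geom$tip_xy[1] - r)):min(nr, ceiling(geom$tip_xy[1] + r))
  cols <- max(1, floor(geom$tip_xy[2] - r)):min(nc, ceiling(geom$tip_xy[2] + r))
  maxima <- NULL
  for (i in rows) for (j in cols) {
    if ((i - geom$tip_xy[1])^2 + (j - geom$tip_xy[2])^2 > r^2) next
    ni <- max(1, i - 1):min(nr, i + 1)
    nj <- max(1, j - 1):min(nc, j + 1)
    nb <- img[ni, nj]
    v <- img[i, j]
    if (v >= max(nb) && v > min(nb)) maxima <- rbind(maxima, c(i, j, v))
  }
  if (is.null(maxima)) return(geom)
  w <- maxima[, 3] / sum(maxima[, 3])
  new_tip <- c(sum(w * maxima[, 1]), sum(w * maxima[, 2]))
  mse <- mean((maxima[, 1] - new_tip[1])^2 + (maxima[, 2] - new_tip[2])^2)
  geom$tip_xy <- new_tip
  geom$tip_radius_px <- max(mse / 2, 1)
  geom$euclidean_D <- sqrt(sum((new_tip - geom$base_xy)^2))
  geom
}

#' Segment one mapping-channel frame
#'
#' Full per-frame segmentation: LoG filtering (response negated so the
#' cell interior is high), auto-thresholding, largest-object selection,
#' erosion/dilation body-protrusion split and optional fragment
#' joining.
#'
#' @param image Numeric matrix, the mapping-channel frame.
#' @param params A \code{\link{segmentation_params}}.
#' @return A \code{frame_segmentation}.
#' @export
segment_frame <- function(image, params = segmentation_params()) {
  resp <- -log_filter(image, params$sigma_log)
  mask_all <- threshold_mask(resp, params$threshold_method,
                             adaptive = params$adaptive,
                             image = image, sigma = params$sigma_log)
  # the LoG response of a homogeneous interior is ~0, so thresholding
  # yields an edge ring; fill holes to recover solid objects
  mask_all <- EBImage::imageData(EBImage::fillHull(mask_all * 1)) > 0.5
  dim(mask_all) <- dim(image)
  main <- extract_cell_mask(mask_all)
  seg <- split_body_protrusions(main, params$ed_iterations, params$element,
                                params$min_protrusion_px)
  if (params$join_fragments) {
    seg$mask <- mask_all
    seg <- join_fragments(seg)
  }
  seg$params <- params
  seg
}

#' Geometry of every attached protrusion in a frame
#'
#' @param seg A \code{frame_segmentation}.
#' @param params A \code{\link{segmentation_params}}.
#' @param measurement_image Optional matrix; when given and
#'   \code{tip_fitting} is TRUE, tips are refined with
#'   \code{\link{fit_tip}}.
#' @param tip_fitting Logical.
#' @return List of \code{protrusion_geometry} (flagged fragments are
#'   omitted).
#' @export
frame_geometries <- function(seg, params = segmentation_params(),
                             measurement_image = NULL,
                             tip_fitting = FALSE) {
  n <- max(seg$protrusion_labels)
  out <- list()
  for (lab in seq_len(n)) {
    if (lab %in% seg$fragment_labels) next
    g <- assign_base_tip(seg, lab, params)
    if (tip_fitting && !is.null(measurement_image)) {
      g <- fit_tip(g, measurement_image)
    }
    out[[length(out) + 1L]] <- g
  }
  out
}

#' Suggest an erosion/dilation iteration count
#'
#' Experimental helper: returns the smallest \code{n} whose opening
#' leaves the foreground area within \code{tol} of the opening at
#' \code{n + 1} (i.e. further erosion removes no more thin structure).
#'
#' @param mask Logical matrix.
#' @param max_n Largest n considered.
#' @param tol Relative area-change tolerance.
#' @return Integer suggestion for \code{ed_iterations}.
#' @export
suggest_ed_iterations <- function(mask, max_n = 12L, tol = 0.005) {
  areas <- vapply(seq_len(max_n + 1L), function(n) {
    er <- morph_n(mask, EBImage::erode, n)
    if (!any(er)) return(NA_real_)
    sum(morph_n(er, EBImage::dilate, n) & mask)
  }, 0)
  for (n in seq_len(max_n)) {
    if (is.na(areas[n]) || is.na(areas[n + 1L])) break
    if (abs(areas[n + 1L] - areas[n]) / areas[n] < tol) return(n)
  }
  max_n
}
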