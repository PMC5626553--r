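# linking, track building, filtering, edits

test_that("link cost follows the distance/overlap formula", {
  g1 <- make_geom(c(10, 10), c(10, 30))
  g2 <- make_geom(c(10, 12), c(10, 33))
  p1 <- 1:50; p2 <- 26:75   # overlap 25
  expect_equal(link_cost(g1, g2, p1, p2, dT = 1), (2 + 3) / 25)
  expect_equal(link_cost(g1, g2, p1, p2, dT = 2), (2 + 3) / 25 * 2)
  # zero overlap is forbidden
  expect_identical(link_cost(g1, g2, 1:10, 11:20), Inf)
})

test_that("identical frames give the identity assignment", {
  entries <- lapply(1:4, function(i)
    list(geom = make_geom(c(10 * i, 10), c(10 * i, 40)),
         pixels = (100 * i):(100 * i + 30)))
  asg <- link_frames(entries, entries)
  expect_equal(asg$links$prev, asg$links$nxt)
  expect_length(asg$births, 0)
  expect_length(asg$deaths, 0)
})

test_that("assignment cost equals brute-force enumeration (3x3)", {
  set.seed(11)
  for (rep in 1:20) {
    C <- matrix(runif(9, 0.1, 10), 3, 3)
    sol <- solve_assignment(C)
    expect_equal(sum(C[cbind(1:3, sol)]),
                 brute_force_assignment_cost(C), tolerance = 1e-12)
  }
})

test_that("zero-overlap candidates are rejected into births/deaths", {
  a <- list(list(geom = make_geom(c(10, 10), c(10, 40)), pixels = 1:30))
  b <- list(list(geom = make_geom(c(10, 11), c(10, 41)), pixels = 100:130))
  asg <- link_frames(a, b)
  expect_equal(nrow(asg$links), 0)
  expect_equal(asg$deaths, 1L)
  expect_equal(asg$births, 1L)
})

test_that("a static protrusion yields a single 10-frame track", {
  entry <- list(geom = make_geom(c(20, 20), c(20, 50)), pixels = 1:40)
  frames <- replicate(10, list(entry), simplify = FALSE)
  tracks <- build_tracks(frames)
  expect_length(tracks, 1)
  expect_equal(tracks[[1]]$frames, 1:10)
})

test_that("crossing filopodia keep their identities via base/tip terms", {
  # two protrusions whose tips approach and cross; masks stay disjoint
  # but each keeps high overlap with itself
  fr <- function(t) {
    list(list(geom = make_geom(c(20, 10), c(20, 30 + t)),
              pixels = 1:40),
         list(geom = make_geom(c(60, 10), c(60 - t, 30)),
              pixels = 101:140))
  }
  frames <- lapply(0:8, fr)
  tracks <- build_tracks(frames)
  expect_length(tracks, 2)
  expect_equal(tracks[[1]]$geoms[[9]]$tip_xy, c(20, 38))
  expect_equal(tracks[[2]]$geoms[[9]]$tip_xy, c(52, 30))
})

test_that("track filtering applies the reference thresholds", {
  sp <- test_sparams()
  # helper: geometric track with controlled perimeter -> length
  len_track <- function(lengths_um, start = 1, id = 1L) {
    per <- lengths_um * 1000 / sp$pixel_size_nm * 2 +
      2 * pi / 4 * 2 * sqrt(2 * log(2)) * sp$sigma_log
    tr <- make_track(rep(list(c(10, 10)), length(lengths_um)),
                     lapply(seq_along(lengths_um), function(i)
                       c(10, 10 + lengths_um[i] * 1000 / sp$pixel_size_nm)),
                     frames = start:(start + length(lengths_um) - 1),
                     track_id = id)
    for (i in seq_along(tr$geoms)) tr$geoms[[i]]$perimeter_px <- per[i]
    tr
  }
  good <- len_track(c(1.0, 1.6, 2.2, 2.6), id = 1L)
  short2 <- len_track(c(2, 2.2), id = 2L)          # only 2 frames
  tiny <- len_track(c(0.7, 0.8, 0.9, 0.9), id = 3L)  # max < 1.8 um
  static <- len_track(rep(2.5, 5), id = 4L)        # no length change
  tracks <- list(good, short2, tiny, static)
  kept <- filter_tracks(tracks, track_filter_params(), sp)
  expect_equal(vapply(kept, `[[`, 0L, "track_id"), 1L)
  # permissive thresholds keep everything, order preserved
  all_kept <- filter_tracks(tracks,
                            track_filter_params(min_frames = 0,
                                                min_max_length_um = 0,
                                                min_length_change_um = 0,
                                                max_mean_waviness = 1), sp)
  expect_equal(vapply(all_kept, `[[`, 0L, "track_id"), 1:4)
})

test_that("edits delete, relink, and round-trip through a file", {
  trA <- make_track(rep(list(c(10, 10)), 10),
                    lapply(1:10, function(i) c(10, 20 + i)),
                    frames = 1:10, track_id = 1L)
  trB <- make_track(rep(list(c(10, 10)), 10),
                    lapply(1:10, function(i) c(10, 31 + i)),
                    frames = 11:20, track_id = 2L)
  trC <- make_track(rep(list(c(40, 10)), 5),
                    lapply(1:5, function(i) c(40, 20 + i)),
                    frames = 1:5, track_id = 3L)
  edits <- data.frame(op = c("relink", "delete"),
                      track_id = c(1L, 3L),
                      frame_from = c(10L, NA), frame_to = c(NA, NA),
                      target_id = c(2L, NA))
  out <- edit_tracks(list(trA, trB, trC), edits)
  expect_length(out, 1)
  expect_equal(out[[1]]$frames, 1:20)
  expect_equal(nrow(attr(out, "edit_log")), 2)
  # dangling references are rejected (so re-application fails loudly)
  expect_error(edit_tracks(out, edits[2, , drop = FALSE]), "no track with id 3")
  # file round trip reproduces the same tracks
  f <- tempfile(fileext = ".csv")
  write_edits(edits, f)
  out2 <- edit_tracks(list(trA, trB, trC), read_edits(f))
  expect_equal(out[[1]]$frames, out2[[1]]$frames)
  expect_equal(length(out2), 1)
})

test_that("delete_range trims frames and drops emptied tracks", {
  tr <- make_track(rep(list(c(10, 10)), 6),
                   lapply(1:6, function(i) c(10, 20 + i)),
                   frames = 1:6, track_id = 7L)
  out <- edit_tracks(list(tr), data.frame(op = "delete_range", track_id = 7L,
                                          frame_from = 4L, frame_to = 6L,
                                          target_id = NA))
  expect_equal(out[[1]]$frames, 1:3)
  out2 <- edit_tracks(out, data.frame(op = "delete_range", track_id = 7L,
                                      frame_from = 1L, frame_to = 3L,
                                      target_id = NA))
  expect_length(out2, 0)
})

test_that("tracking fixture: links match ground truth with drift", {
  spec <- movie_spec(width = 300, height = 300, n_frames = 25, seed = 5,
                     noise_sd = 4, body_radius_px = 35,
                     body_center = c(150, 150),
                     filopodia = lapply(0:5, function(k) list(
                       angle_deg = k * 60,
                       velocity_nm_s = 40,
                       initial_length_um = 1.5 + 0.3 * k,
                       drift_deg_per_frame = (k %% 3 - 1) * 0.8)))
  mv <- generate_movie(spec)
  sp <- test_sparams()
  frames <- lapply(mv$mapping, function(im)
    frame_protrusions(segment_frame(im, sp), sp))
  tracks <- build_tracks(frames)
  truth <- mv$truth
  assign_id <- function(tr, i) {
    t <- tr$frames[i]
    tt <- truth[truth$frame == t, ]
    d <- sqrt((tt$tip_row - tr$geoms[[i]]$tip_xy[1])^2 +
                (tt$tip_col - tr$geoms[[i]]$tip_xy[2])^2)
    tt$filo_id[which.min(d)]
  }
  good <- 0; total <- 0
  for (tr in tracks) {
    if (length(tr$frames) < 2) next
    ids <- vapply(seq_along(tr$frames), assign_id, 0, tr = tr)
    good <- good + sum(ids[-1] == ids[-length(ids)])
    total <- total + length(ids) - 1
  }
  expect_gt(total, 100)
  expect_gte(good / total, 0.99)
})
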