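# body/protrusion splitting, fragments, base/tip geometry

test_that("largest component is kept, with a deterministic tie-break", {
  m <- matrix(FALSE, 40, 40)
  m[5:14, 5:14] <- TRUE    # 100 px
  m[25:30, 25:29] <- TRUE  # 30 px
  kept <- extract_cell_mask(m)
  expect_equal(sum(kept), 100)
  expect_true(all(which(kept) %in% which(m)))
  # equal sizes: first component in scan order wins, reproducibly
  m2 <- matrix(FALSE, 20, 20)
  m2[2:4, 2:4] <- TRUE
  m2[10:12, 10:12] <- TRUE
  expect_identical(extract_cell_mask(m2), extract_cell_mask(m2))
  expect_equal(sum(extract_cell_mask(m2)), 9)
  expect_error(extract_cell_mask(matrix(FALSE, 5, 5)), "no object")
})

test_that("labeling is 8-connected", {
  m <- matrix(FALSE, 6, 6)
  m[2, 2] <- TRUE; m[3, 3] <- TRUE  # touch only diagonally
  expect_equal(max(label8(m)), 1L)
})

test_that("erosion/dilation splits protrusions from the body", {
  m <- disk_with_arms(arms = list(
    list(dir = "E", width = 3, length = 10),
    list(dir = "N", width = 3, length = 10),
    list(dir = "S", width = 3, length = 10)))
  seg <- split_body_protrusions(m, 4)
  expect_equal(max(seg$protrusion_labels), 3)
  expect_length(seg$fragment_labels, 0)
  # no protrusions on a bare disk
  seg0 <- split_body_protrusions(disk_mask(80, 80, c(40, 40), 30), 4)
  expect_equal(max(seg0$protrusion_labels), 0)
  # over-erosion errors rather than returning empty masks
  tiny <- disk_mask(20, 20, c(10, 10), 3)
  expect_error(split_body_protrusions(tiny, 8), "over-erosion")
})

test_that("partition property holds: body and protrusions disjoint, within mask", {
  m <- disk_with_arms(arms = list(list(dir = "E", width = 5, length = 15),
                                  list(dir = "W", width = 3, length = 12)))
  seg <- split_body_protrusions(m, 4)
  prot <- seg$protrusion_labels > 0
  expect_false(any(seg$body_mask & prot))
  expect_true(all((seg$body_mask | prot) == m))
})

test_that("wider protrusions need more erosion iterations", {
  m <- disk_with_arms(nr = 160, nc = 160, center = c(80, 80), radius = 35,
                      arms = list(list(dir = "E", width = 9, length = 30)))
  seg3 <- split_body_protrusions(m, 3)
  seg6 <- split_body_protrusions(m, 6)
  expect_equal(max(seg3$protrusion_labels), 0)  # 9-px arm survives opening
  expect_gt(max(seg6$protrusion_labels), 0)
})

test_that("protrusion pixel count is monotone in ed_iterations", {
  m <- disk_with_arms(arms = list(list(dir = "E", width = 3, length = 12),
                                  list(dir = "N", width = 5, length = 12)))
  counts <- sapply(1:6, function(n)
    sum(split_body_protrusions(m, n)$protrusion_labels > 0))
  expect_true(all(diff(counts) >= 0))
})

test_that("base and tip land at the junction and distal end", {
  m <- disk_with_arms(arms = list(list(dir = "E", width = 3, length = 10)))
  seg <- split_body_protrusions(m, 4)
  g <- assign_base_tip(seg, 1, test_sparams())
  expect_lt(abs(g$base_xy[1] - 60), 1.5)       # on the arm midline
  expect_equal(g$tip_xy[1], 60, tolerance = 1.01)
  expect_equal(g$tip_xy[2], 100, tolerance = 1.01)  # distal end
  expect_gt(g$euclidean_D, 8)
  expect_error(assign_base_tip(seg, 99), "no protrusion")
})

test_that("fragments are flagged and joined back along the axis", {
  m <- disk_with_arms(arms = list(list(dir = "E", width = 3, length = 6)))
  # detached distal fragment with a 3-px gap along the same axis
  m[59:61, 100:108] <- TRUE
  seg <- split_body_protrusions(m, 4)
  expect_length(seg$fragment_labels, 1)
  joined <- join_fragments(seg)
  expect_length(joined$fragment_labels, 0)
  expect_equal(max(joined$protrusion_labels), 1)
  g <- assign_base_tip(joined, 1, test_sparams())
  expect_equal(g$tip_xy[2], 108, tolerance = 1.01)  # distal fragment's tip
  # no fragments: unchanged
  seg2 <- split_body_protrusions(
    disk_with_arms(arms = list(list(dir = "E", width = 3, length = 10))), 4)
  expect_identical(join_fragments(seg2), seg2)
})

test_that("close fragment pairs join each other before the body", {
  m <- disk_with_arms(arms = list(list(dir = "E", width = 3, length = 4)))
  m[59:61, 98:103] <- TRUE    # fragment 1, 4 px from arm end
  m[59:61, 106:112] <- TRUE   # fragment 2, 3 px from fragment 1
  seg <- split_body_protrusions(m, 4)
  expect_equal(length(seg$fragment_labels), 2)
  joined <- join_fragments(seg)
  expect_length(joined$fragment_labels, 0)
  expect_equal(max(joined$protrusion_labels), 1)
})

test_that("tip fitting relocates onto a bright spot and clamps radius", {
  # wide arm so the search radius sqrt((area/2)/pi) reaches past 4 px
  m <- disk_with_arms(arms = list(list(dir = "E", width = 5, length = 25)))
  seg <- split_body_protrusions(m, 4)
  g <- assign_base_tip(seg, 1, test_sparams())
  img <- matrix(10, 120, 120)
  spot <- round(g$tip_xy) + c(0, 4)   # 4 px distal of mapped tip
  img[spot[1], spot[2]] <- 200
  img[spot[1], spot[2] + 1] <- 200
  g2 <- fit_tip(g, img)
  expect_lt(sqrt(sum((g2$tip_xy - (spot + c(0, 0.5)))^2)), 1.01)
  # uniform channel: unchanged
  g3 <- fit_tip(g, matrix(50, 120, 120))
  expect_identical(g3$tip_xy, g$tip_xy)
  # radius formula bounds
  expect_equal(min(max(sqrt((2 * pi * 25) / 2 / pi), 3), 20), 5)
  expect_equal(min(max(sqrt((1e6 / 2) / pi), 3), 20), 20)
})

test_that("segmentation recovers ground truth masks on a clean fixture", {
  spec <- movie_spec(n_frames = 1, seed = 21, noise_sd = 0,
                     filopodia = list(
                       list(angle_deg = 15, velocity_nm_s = 0,
                            initial_length_um = 3),
                       list(angle_deg = 150, velocity_nm_s = 0,
                            initial_length_um = 2.5)))
  mv <- generate_movie(spec)
  seg <- segment_frame(mv$mapping[[1]], test_sparams())
  truth_mask <- mv$mapping[[1]] > 100
  got <- seg$body_mask | seg$protrusion_labels > 0
  iou <- sum(got & truth_mask) / sum(got | truth_mask)
  expect_gte(iou, 0.95)
  expect_equal(max(seg$protrusion_labels), 2)
})

test_that("speckle noise does not corrupt the cell mask", {
  spec <- movie_spec(n_frames = 1, seed = 22, noise_sd = 0,
                     filopodia = list(list(angle_deg = 80,
                                           velocity_nm_s = 0,
                                           initial_length_um = 3)))
  mv <- generate_movie(spec)
  img <- mv$mapping[[1]]
  set.seed(9)
  # bright speckles away from the cell
  for (i in 1:25) {
    r <- sample(1:15, 1); c <- sample(1:220, 1)
    img[r, c] <- 220
  }
  seg <- segment_frame(img, test_sparams())
  truth_mask <- mv$mapping[[1]] > 100
  got <- seg$body_mask | seg$protrusion_labels > 0
  disagree <- sum(xor(got, truth_mask)) / sum(truth_mask)
  expect_lt(disagree, 0.02)
})
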