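make_person <- function(uv, conf = rep(0.8, nrow(uv))) {
  p <- matrix(0, 25, 3)
  p[seq_len(nrow(uv)), 1:2] <- uv
  p[seq_len(nrow(uv)), 3] <- conf
  p
}

test_that("median_point is the componentwise median of valid keypoints", {
  p <- make_person(rbind(c(0, 0), c(10, 20), c(100, 40)))
  expect_equal(median_point(p), c(10, 20))

  none <- matrix(c(5, 5, 0), 25, 3, byrow = TRUE)   # all confidence 0
  expect_null(median_point(none))

  # matches a brute-force sort-and-pick oracle on full 25-keypoint people
  set.seed(31)
  for (i in 1:10) {
    p <- cbind(stats::runif(25, 0, 1920), stats::runif(25, 0, 1080),
               stats::runif(25))
    keep <- p[, 3] > 0.4
    oracle <- c(sort(p[keep, 1])[ceiling(sum(keep) / 2):ceiling((sum(keep) + 1) / 2)],
                sort(p[keep, 2])[ceiling(sum(keep) / 2):ceiling((sum(keep) + 1) / 2)])
    m <- median_point(p, min_confidence = 0.4)
    expect_equal(m[1], mean(oracle[seq_len(length(oracle) / 2)]))
  }
})

test_that("column bounding boxes match per-corner projection", {
  cal <- camera_calibration(1000, 1000, 960, 540,
                            R = diag(3), t = c(0, -1.1, 6))
  # column centred on the optical axis: bbox symmetric about (cx, cy)
  bb <- project_column_bbox(cal, centre = c(0, 0), cell_size = 0.25,
                            z_range = c(0, 2.2))
  expect_equal(unname(bb["x0"] + bb["x1"]) / 2, 960, tolerance = 1e-9)

  # column behind the camera is not visible
  cal2 <- camera_calibration(1000, 1000, 960, 540, t = c(0, 0, -10))
  expect_null(project_column_bbox(cal2, c(0, 0)))

  # random columns/cameras equal the min/max of individually projected corners
  set.seed(33)
  for (i in 1:10) {
    cal3 <- random_camera(target = c(0, 0, 1), radius = 6)
    ctr <- stats::runif(2, -1, 1)
    bb <- project_column_bbox(cal3, ctr)
    corners <- as.matrix(expand.grid(x = ctr[1] + c(-0.125, 0.125),
                                     y = ctr[2] + c(-0.125, 0.125),
                                     z = c(0, 2.2)))
    uv <- t(apply(corners, 1, function(X) project(cal3, X)))
    expect_equal(unname(bb["x0"]), max(min(uv[, 1]), 0), tolerance = 1e-9)
    expect_equal(unname(bb["y1"]), min(max(uv[, 2]), 1080), tolerance = 1e-9)
  }
})

test_that("occupancy scores are containment counts over visibility counts", {
  sc <- noiseless_scene(n_cameras = 4, duration = 0.05)
  grid <- make_occupancy_grid(occupancy_grid_spec(c(0, 3), c(-1, 1)), sc$rig)
  det <- lapply(sc$det, function(fr) fr[[1]]$people)
  occ <- compute_occupancy(det, grid)
  expect_true(all(occ$m <= occ$v))
  expect_true(all(occ$o >= 0 & occ$o <= 1, na.rm = TRUE))
  expect_equal(occ$o[!is.na(occ$o)],
               (occ$m / occ$v)[!is.na(occ$o)])
  # score 1 iff every camera that sees the column has a median inside it
  full <- which(!is.na(occ$o) & occ$o == 1)
  expect_true(all(occ$m[full] == occ$v[full]))
  # the occupancy dump carries one row per column
  df <- occupancy_as_data_frame(occ)
  expect_equal(nrow(df), nrow(grid$centres))
})

test_that("columns seen by too few views are excluded", {
  cfg <- scene_config(n_cameras = 2, ring_radius = 2, volume_centre = c(0, 0, 1))
  rig <- make_rig(cfg)
  # a footprint far outside both frusta has no visible columns
  grid <- make_occupancy_grid(occupancy_grid_spec(c(40, 42), c(40, 42)), rig)
  occ <- compute_occupancy(list(cam1 = list(), cam2 = list()), grid)
  expect_true(all(is.na(occ$o[grid$visibility == 0])))
})

test_that("the occupancy peak sits at the true person position", {
  sc <- noiseless_scene(n_cameras = 6, duration = 0.05)
  grid <- make_occupancy_grid(
    occupancy_grid_spec(c(-1, 12), c(-2, 2)), sc$rig)
  det <- lapply(sc$det, function(fr) fr[[1]]$people)
  occ <- compute_occupancy(det, grid)
  peak <- which.max(ifelse(is.na(occ$o), -1, occ$o) +
                      occ$v * 1e-9)     # deterministic among ties
  truth_xy <- sc$mot$truth[1, 9, 1:2]   # MidHip ground position, frame 1
  groups <- group_detections(occ)
  expect_length(groups, 1)
  expect_lt(sqrt(sum((groups[[1]]$ground - truth_xy)^2)), 0.26)
  expect_gte(nrow(groups[[1]]$members), 2)
})

test_that("an empty scene yields no groups", {
  cfg <- scene_config(n_cameras = 4)
  rig <- make_rig(cfg)
  grid <- make_occupancy_grid(occupancy_grid_spec(c(-1, 12), c(-2, 2)), rig)
  det <- stats::setNames(rep(list(list()), 4), names(rig))
  occ <- compute_occupancy(det, grid)
  expect_equal(group_detections(occ), list())
})

test_that("two people 2 m apart form two complete groups in every frame", {
  sc <- noiseless_scene(n_cameras = 6, duration = 0.05, n_people = 2)
  grid <- make_occupancy_grid(
    occupancy_grid_spec(c(-1, 12), c(-3, 3)), sc$rig)
  for (f in c(1, 5, 10)) {
    det <- lapply(sc$det, function(fr) fr[[f]]$people)
    occ <- compute_occupancy(det, grid)
    groups <- group_detections(occ)
    expect_length(groups, 2)
    # every view that detected both people contributes to both groups
    for (g in groups) expect_gte(nrow(g$members), 2)
    # each view appears at most once per group, and claims are disjoint
    for (g in groups)
      expect_false(anyDuplicated(g$members$view) > 0)
    keys <- unlist(lapply(groups, function(g)
      paste(g$members$view, g$members$person)))
    expect_false(anyDuplicated(keys) > 0)
  }
})

test_that("grouping is invariant to camera order", {
  sc <- noiseless_scene(n_cameras = 5, duration = 0.05)
  spec <- occupancy_grid_spec(c(-1, 12), c(-2, 2))
  det <- lapply(sc$det, function(fr) fr[[1]]$people)

  g1 <- group_detections(compute_occupancy(det, make_occupancy_grid(spec, sc$rig)))
  perm <- c(3, 1, 5, 2, 4)
  g2 <- group_detections(compute_occupancy(
    det[perm], make_occupancy_grid(spec, sc$rig[perm])))
  expect_length(g1, length(g2))
  expect_equal(g1[[1]]$ground, g2[[1]]$ground)
  # same (camera, person) membership after unpermuting view indices
  m1 <- sort(paste(names(sc$rig)[g1[[1]]$members$view], g1[[1]]$members$person))
  m2 <- sort(paste(names(sc$rig[perm])[g2[[1]]$members$view], g2[[1]]$members$person))
  expect_equal(m1, m2)
})
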