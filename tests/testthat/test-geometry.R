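test_that("pinhole projection follows the camera model", {
  cal <- camera_calibration(fx = 1000, fy = 1000, cx = 960, cy = 540)
  # optical axis maps to the principal point at any depth
  expect_equal(project(cal, c(0, 0, 1)), c(960, 540))
  expect_equal(project(cal, c(0, 0, 7.3)), c(960, 540))
  # plain pinhole arithmetic
  expect_equal(project(cal, c(0.1, 0, 1)), c(1060, 540))
  expect_error(project(cal, c(0, 0, -1)), "behind")
})

test_that("distortion matches direct evaluation of the polynomial", {
  cal <- camera_calibration(fx = 1000, fy = 1000, cx = 960, cy = 540,
                            k1 = -0.1, k2 = 0.01, p1 = 1e-3, p2 = -5e-4)
  X <- c(0.1, -0.05, 1)
  x <- X[1] / X[3]
  y <- X[2] / X[3]
  r2 <- x^2 + y^2
  radial <- 1 + cal$k1 * r2 + cal$k2 * r2^2
  xd <- x * radial + 2 * cal$p1 * x * y + cal$p2 * (r2 + 2 * x^2)
  yd <- y * radial + cal$p1 * (r2 + 2 * y^2) + 2 * cal$p2 * x * y
  expect_equal(project(cal, X), c(1000 * xd + 960, 1000 * yd + 540),
               tolerance = 1e-12)
})

test_that("backproject inverts project for random cameras and points", {
  set.seed(42)
  for (i in 1:20) {
    cal <- random_camera(distortion = i %% 2 == 0)
    X <- c(stats::runif(1, -1, 1), stats::runif(1, -1, 1),
           stats::runif(1, 0.3, 1.8))
    uv <- project(cal, X)
    r <- backproject(cal, uv)
    d <- ray_point_distance(matrix(r$origin), matrix(r$direction), X)
    expect_lt(d, 1e-9)
    # and the ray re-projects onto the original pixel
    pt <- r$origin + 2 * r$direction *
      sum((X - r$origin) * r$direction) / 2
    expect_lt(max(abs(project(cal, pt) - uv)), 1e-6)
  }
})

test_that("pixel at the principal point backprojects along the optical axis", {
  cal <- camera_calibration(fx = 1200, fy = 1100, cx = 960, cy = 540)
  r <- backproject(cal, c(960, 540))
  expect_equal(r$direction, c(0, 0, 1), tolerance = 1e-12)
  expect_equal(r$origin, c(0, 0, 0))
})

test_that("calibration constructor rejects invalid rotations", {
  R_bad <- diag(3)
  R_bad[1, 1] <- 1.01
  expect_error(camera_calibration(1000, 1000, 960, 540, R = R_bad),
               "orthonormal")
  expect_error(camera_calibration(-5, 1000, 960, 540), "positive")
})

test_that("intersect_rays recovers exact and skew-ray solutions", {
  p <- c(1, 2, 3)
  r1 <- ray3d(p - c(5, 0, 0), c(1, 0, 0))
  r2 <- ray3d(p - c(0, 5, 0), c(0, 1, 0))
  fit <- intersect_rays(list(r1, r2))
  expect_equal(fit$point, p, tolerance = 1e-12)
  expect_equal(fit$residuals, c(0, 0), tolerance = 1e-12)

  # two skew rays: the midpoint of the common perpendicular segment
  s1 <- ray3d(c(0, 0, 0), c(1, 0, 0))      # z = 0 line along x
  s2 <- ray3d(c(0, -5, 1), c(0, 1, 0))     # z = 1 line along y at x = 0
  fit2 <- intersect_rays(list(s1, s2))
  expect_equal(fit2$point, c(0, 0, 0.5), tolerance = 1e-12)
  expect_equal(fit2$residuals, c(0.5, 0.5), tolerance = 1e-12)

  set.seed(7)
  rays <- rays_through_point(p, 5)
  expect_equal(intersect_rays(rays)$point, p, tolerance = 1e-9)
})

test_that("intersect_rays is invariant to ray order and origin sliding", {
  set.seed(11)
  p <- stats::rnorm(3)
  rays <- rays_through_point(p, 6, perturb = 0.02)
  f1 <- intersect_rays(rays)
  f2 <- intersect_rays(rev(rays))
  expect_equal(f1$point, f2$point, tolerance = 1e-12)
  slid <- lapply(rays, function(r)
    ray3d(r$origin + stats::runif(1, -2, 2) * r$direction, r$direction))
  expect_equal(intersect_rays(slid)$point, f1$point, tolerance = 1e-9)
})

test_that("parallel rays raise a degenerate-geometry error", {
  r1 <- ray3d(c(0, 0, 0), c(1, 0, 0))
  r2 <- ray3d(c(0, 1, 0), c(1, 0, 0))
  expect_error(intersect_rays(list(r1, r2)), "parallel")
})

test_that("ransac_triangulate handles clean, minimal and contaminated sets", {
  set.seed(13)
  p <- c(2, -1, 1.2)
  clean <- rays_through_point(p, 6)
  rt <- ransac_triangulate(clean)
  expect_true(rt$ok)
  expect_true(all(rt$inliers))
  expect_equal(rt$point, intersect_rays(clean)$point, tolerance = 1e-12)

  # minimal two-ray case
  rt2 <- ransac_triangulate(clean[1:2])
  expect_true(rt2$ok)
  expect_true(all(rt2$inliers))

  # 4 consistent rays + 2 gross outliers displaced >= 0.5 m
  out <- rays_through_point(p + c(0.8, 0, 0), 2)
  rt3 <- ransac_triangulate(c(clean[1:4], out), inlier_threshold = 0.04)
  expect_true(rt3$ok)
  expect_equal(which(rt3$inliers), 1:4)
  expect_lt(sqrt(sum((rt3$point - p)^2)), 0.04)
})

test_that("ransac recovers the point under noise and <= 40% outliers", {
  # threshold at 5x the nominal noise scale; the estimate must land within
  # 2x the realised inlier residual scale of the true point
  noise <- 0.004
  fails <- 0
  for (s in 1:100) {
    set.seed(s)
    p <- stats::rnorm(3)
    rays <- c(rays_through_point(p, 6, perturb = noise),
              rays_through_point(p + c(0.7, 0.2, 0), 4, perturb = noise))
    rt <- ransac_triangulate(rays, inlier_threshold = 5 * noise)
    # realised inlier noise: RMS distance of the 6 true rays from truth
    O <- vapply(rays[1:6], function(r) r$origin, numeric(3))
    D <- vapply(rays[1:6], function(r) r$direction, numeric(3))
    lim <- 2 * sqrt(mean(ray_point_distance(O, D, p)^2))
    if (!rt$ok || sqrt(sum((rt$point - p)^2)) > lim) fails <- fails + 1
  }
  expect_equal(fails, 0)
})

test_that("rigid alignment recovers exact transforms and noise floors", {
  set.seed(17)
  pts <- matrix(stats::rnorm(300), ncol = 3)
  expect_equal(estimate_rigid_alignment(pts, pts)$rotation, diag(3),
               tolerance = 1e-12)

  Rz <- matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3)  # 90 deg about z
  tgt <- pts %*% t(Rz) + matrix(c(1, 2, 3), 100, 3, byrow = TRUE)
  tf <- estimate_rigid_alignment(pts, tgt)
  expect_equal(tf$rotation, Rz, tolerance = 1e-9)
  expect_equal(tf$translation, c(1, 2, 3), tolerance = 1e-9)
  expect_equal(apply_transform(tf, pts), tgt, tolerance = 1e-9)

  # arbitrary proper rotations are exact on noiseless data
  for (i in 1:10) {
    R <- random_rotation()
    t <- stats::rnorm(3)
    tgt <- pts %*% t(R) + matrix(t, 100, 3, byrow = TRUE)
    tf <- estimate_rigid_alignment(pts, tgt)
    expect_lt(max(abs(tf$rotation - R)), 1e-9)
  }

  # 1 mm noise: RMS residual at the propagated noise level
  noisy <- tgt + matrix(stats::rnorm(300, sd = 1e-3), ncol = 3)
  tf2 <- estimate_rigid_alignment(pts, noisy)
  rms <- sqrt(mean(rowSums((apply_transform(tf2, pts) - noisy)^2)))
  expect_gt(rms, 0.5e-3)
  expect_lt(rms, 3e-3)

  expect_error(estimate_rigid_alignment(pts[1:2, ], tgt[1:2, ]), "3 paired")
  line <- cbind(1:10, 2 * (1:10), 3 * (1:10))
  expect_error(estimate_rigid_alignment(line, line + 1), "collinear")
})

test_that("scale validation is exact on constant and reconstructed wands", {
  a <- matrix(rep(c(0, 0, 1), each = 50), ncol = 3)
  b <- matrix(rep(c(0.6014, 0, 1), each = 50), ncol = 3)
  vs <- validate_scale(a, b)
  expect_equal(vs$mean_error_mm, 0)
  expect_equal(vs$sd_mm, 0)
  expect_error(validate_scale(a[1:10, ], b), "equal length")

  # noisy endpoints: SD on the order of the propagated noise
  set.seed(23)
  sds <- replicate(20, {
    an <- a + matrix(stats::rnorm(150, sd = 1e-3), ncol = 3)
    bn <- b + matrix(stats::rnorm(150, sd = 1e-3), ncol = 3)
    validate_scale(an, bn)$sd_mm
  })
  # difference of two 1 mm-noise endpoints projected on the axis: ~1.4 mm
  expect_gt(median(sds), 0.7)
  expect_lt(median(sds), 3)
})
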