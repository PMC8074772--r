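test_that("segment parameter tables are well-formed", {
  for (sex in c("male", "female")) {
    tab <- de_leva_parameters(sex)
    expect_equal(sum(tab$mass_fraction), 1, tolerance = 1e-9)
    expect_true(all(tab$com_ratio >= 0 & tab$com_ratio <= 1))
    expect_true(all(tab$proximal %in% 1:25))
    expect_true(all(tab$distal %in% 1:25))
  }
  # sexes differ (sex-specific tables, not a shared copy)
  expect_false(isTRUE(all.equal(de_leva_parameters("male")$mass_fraction,
                                de_leva_parameters("female")$mass_fraction)))
})

test_that("a single-segment model reduces CoM to the segment point", {
  single <- data.frame(segment = "only", mass_fraction = 1, com_ratio = 0.5,
                       proximal = 10, distal = 11)    # RHip -> RKnee
  skel <- matrix(stats::rnorm(75), 25, 3)
  expect_equal(com_from_keypoints(skel, single),
               (skel[10, ] + skel[11, ]) / 2, tolerance = 1e-12)
})

test_that("CoM matches a brute-force weighted-sum oracle", {
  set.seed(61)
  tab <- de_leva_parameters("female")
  for (i in 1:20) {
    skel <- matrix(stats::rnorm(75, sd = 0.5), 25, 3)
    oracle <- c(0, 0, 0)
    for (s in seq_len(nrow(tab))) {
      p <- skel[tab$proximal[s], ]
      d <- skel[tab$distal[s], ]
      oracle <- oracle + tab$mass_fraction[s] * (p + tab$com_ratio[s] * (d - p))
    }
    expect_equal(com_from_keypoints(skel, tab), oracle, tolerance = 1e-12)
  }
})

test_that("a mirror-symmetric pose has its CoM on the symmetry plane", {
  pose <- simulate_motion(scene_config(profile = "static",
                                       duration = 0.01))$truth[1, , ]
  nm <- body25_names()
  # symmetrize: average each left/right pair across y = y0
  left <- grep("^L", nm)
  right <- match(sub("^L", "R", nm[left]), nm)
  y0 <- pose[match("MidHip", nm), 2]
  for (k in seq_along(left)) {
    mid <- (pose[left[k], ] + pose[right[k], ]) / 2
    off <- (pose[left[k], 2] - pose[right[k], 2]) / 2
    pose[left[k], ] <- c(mid[1], y0 + off, mid[3])
    pose[right[k], ] <- c(mid[1], y0 - off, mid[3])
  }
  pose[-c(left, right), 2] <- y0
  com <- com_from_keypoints(pose)
  expect_equal(com[2], y0, tolerance = 1e-12)
})

test_that("CoM is equivariant under rigid motion and inside the point cloud", {
  set.seed(67)
  skel <- simulate_motion(scene_config(profile = "static",
                                       duration = 0.01))$truth[1, , ]
  com <- com_from_keypoints(skel)
  u <- c(1.5, -2, 0.7)
  expect_equal(com_from_keypoints(sweep(skel, 2, u, "+")), com + u,
               tolerance = 1e-9)
  R <- random_rotation()
  expect_equal(com_from_keypoints(skel %*% t(R)), as.numeric(R %*% com),
               tolerance = 1e-9)
  # convex combination: inside the bounding box of the keypoints used
  expect_true(all(com >= apply(skel, 2, min) & com <= apply(skel, 2, max)))
})

test_that("missing endpoints propagate as CoM gaps unless mirrored", {
  skel <- simulate_motion(scene_config(profile = "static",
                                       duration = 0.01))$truth[1, , ]
  nm <- body25_names()
  skel[match("LKnee", nm), ] <- NA
  expect_true(anyNA(com_from_keypoints(skel)))
  filled <- com_from_keypoints(skel, mirror_missing = TRUE)
  expect_false(anyNA(filled))
  # the mirrored reconstruction stays close to the intact-pose CoM
  intact <- com_from_keypoints(
    simulate_motion(scene_config(profile = "static",
                                 duration = 0.01))$truth[1, , ])
  expect_lt(sqrt(sum((filled - intact)^2)), 0.05)
})

test_that("central differences are exact for quadratics and flag endpoints", {
  rate <- 200
  t <- (0:99) / rate
  x <- t^2
  v <- central_difference_velocity(x, rate)
  expect_equal(v[2:99], 2 * t[2:99], tolerance = 1e-9)
  expect_equal(attr(v, "one_sided"), c(1L, 100L))
  expect_equal(central_difference_velocity(rep(5, 10), rate),
               rep(0, 10), ignore_attr = TRUE)

  # sine: max error bounded by the third-derivative Taylor term
  xs <- sin(2 * pi * t)
  vs <- central_difference_velocity(xs, rate)
  err <- max(abs(vs[2:99] - 2 * pi * cos(2 * pi * t[2:99])))
  bound <- (2 * pi / rate)^2 / 6 * (2 * pi)^3 * 1.01
  expect_lt(err, bound)

  # a gap inside the stencil leaves the velocity undefined there; the
  # central stencil at the gap itself does not include the gapped sample
  xg <- x
  xg[50] <- NA
  vg <- central_difference_velocity(xg, rate)
  expect_true(all(is.na(vg[c(49, 51)])))
  expect_false(anyNA(vg[c(2:48, 50, 52:99)]))
})

test_that("flight-phase fit recovers the generating acceleration", {
  rate <- 200
  t <- (0:79) / rate
  z <- 1.2 + 3 * t - 9.81 * t^2 / 2
  g <- flight_phase_gravity_check(z, rate)
  expect_equal(as.numeric(g), -9.81, tolerance = 1e-9)

  expect_equal(as.numeric(flight_phase_gravity_check(1 + 0.5 * t, rate)), 0,
               tolerance = 1e-9)
  expect_error(flight_phase_gravity_check(z, rate, window = 1:4),
               "at least 5")

  # 2 mm position noise, 0.3 s window: mean over 100 seeds within 0.1 m/s^2
  t3 <- (0:59) / rate
  z3 <- 1.2 + 3 * t3 - 9.81 * t3^2 / 2
  fits <- vapply(1:100, function(s) {
    set.seed(s)
    as.numeric(flight_phase_gravity_check(z3 + stats::rnorm(60, sd = 2e-3),
                                          rate))
  }, numeric(1))
  expect_lt(abs(mean(fits) + 9.81), 0.1)
})
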