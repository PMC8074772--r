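test_that("butterworth filter has unit DC gain and zero lag", {
  expect_equal(butterworth_lowpass(rep(3.7, 60), 12, 200), rep(3.7, 60),
               tolerance = 1e-9)

  # 1 Hz sine at 200 Hz through a 12 Hz dual-pass filter: gain within 1%,
  # peak cross-correlation at zero lag
  t <- seq(0, 4, by = 1 / 200)
  x <- sin(2 * pi * 1 * t)
  y <- butterworth_lowpass(x, 12, 200)
  core <- 101:(length(t) - 100)
  gain <- max(abs(y[core])) / 1
  expect_lt(abs(gain - 1), 0.01)
  cc <- stats::ccf(y[core], x[core], lag.max = 10, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)

  # 50 Hz sine: attenuated below 1% (analytic |H|^2 at ratio 50/12 is ~1e-5)
  x50 <- sin(2 * pi * 50 * t)
  y50 <- butterworth_lowpass(x50, 12, 200)
  expect_lt(max(abs(y50[core])), 0.01)
})

test_that("butterworth output is zero-phase under time reversal", {
  set.seed(41)
  x <- cumsum(stats::rnorm(200))
  y <- butterworth_lowpass(x, 10, 100)
  yr <- rev(butterworth_lowpass(rev(x), 10, 100))
  expect_equal(y, yr, tolerance = 1e-9)
})

test_that("butterworth rejects NaN input and bad cutoffs", {
  x <- stats::rnorm(50)
  x[10] <- NA
  expect_error(butterworth_lowpass(x, 12, 200), "interpolate")
  expect_error(butterworth_lowpass(stats::rnorm(50), 120, 200), "cutoff")
  expect_error(butterworth_lowpass(stats::rnorm(5), 12, 200), "short")
})

test_that("autocorrelation cutoff selection tracks the signal band", {
  # 2 Hz sine + white noise: selected cutoff near the lowest cutoff that
  # passes the signal (median over 20 seeds)
  t <- seq(0, 2, by = 1 / 200)
  sel <- vapply(1:20, function(s) {
    set.seed(s)
    x <- sin(2 * pi * 2 * t) + stats::rnorm(length(t), sd = 0.1)
    select_cutoff_autocorrelation(x, 200)
  }, numeric(1))
  expect_gte(stats::median(sel), 2)
  expect_lte(stats::median(sel), 6)

  # pure white noise: everything is residual, the selection sits at the
  # low end of the grid where the residual is closest to the full noise
  seln <- vapply(1:20, function(s) {
    set.seed(100 + s)
    select_cutoff_autocorrelation(stats::rnorm(400), 200)
  }, numeric(1))
  expect_lte(stats::median(seln), 4)

  # a noiseless sine is passed untouched at the selected cutoff
  x <- sin(2 * pi * 1 * t)
  fc <- select_cutoff_autocorrelation(x, 200)
  expect_gt(fc, 1)
  resid <- x - butterworth_lowpass(x, fc, 200)
  expect_lt(stats::var(resid), 1e-10 * stats::var(x))

  expect_error(select_cutoff_autocorrelation(x, 200, numeric(0)), "empty")
})

test_that("kalman smoother is exact on a model-matched noiseless ramp", {
  t <- (0:199) / 200
  x <- 0.3 + 1.7 * t                 # constant velocity
  sm <- kalman_smooth(x, 200, kalman_config("cv", q = 1, r = 1e-6))
  expect_lt(max(abs(sm$x[6:200] - x[6:200])), 1e-6)
})

test_that("smoothing reduces RMSE on noisy constant-velocity data", {
  t <- (0:299) / 200
  truth <- 2 * t
  wins <- 0
  for (s in 1:100) {
    set.seed(s)
    y <- truth + stats::rnorm(300, sd = 0.02)
    sm <- kalman_smooth(y, 200, kalman_config("cv", q = 1, r = 0.02^2))
    if (sqrt(mean((sm$x - truth)^2)) < sqrt(mean((y - truth)^2)))
      wins <- wins + 1
  }
  expect_gte(wins, 95)
})

test_that("smoothed variance never exceeds the forward-filtered variance", {
  set.seed(43)
  y <- cumsum(stats::rnorm(150, 0.01)) + stats::rnorm(150, sd = 0.05)
  sm <- kalman_smooth(y, 100, kalman_config("cv", q = 5, r = 2.5e-3))
  expect_true(all(sm$var <= sm$filtered_var + 1e-12))
  # the smoother reduces to the forward filter at the final sample
  n <- length(y)
  expect_equal(sm$x[n], sm$filtered[n])
  expect_equal(sm$var[n], sm$filtered_var[n])
})

test_that("the vectorized CV path matches the reference smoother", {
  set.seed(47)
  cfg <- kalman_config("cv", q = 3, r = 0.01)
  y <- cumsum(stats::rnorm(80, 0.05)) + stats::rnorm(80, sd = 0.1)
  y[c(10:14, 50)] <- NA                 # gaps: skipped measurement updates
  fast <- kalman_smooth(y, 100, cfg)
  ref <- com3d:::kalman_smooth_ref(y, 100, cfg)
  expect_equal(fast$x, ref$x, tolerance = 1e-12)
  expect_equal(fast$var, ref$var, tolerance = 1e-12)
  expect_equal(fast$velocity, ref$state[2, ], tolerance = 1e-12)
  # gaps are bridged with finite estimates and inflated variance
  expect_true(all(is.finite(fast$x)))
  expect_gt(mean(fast$var[10:14]), mean(fast$var[20:24]))
})

test_that("the constant-acceleration model is available and sane", {
  t <- (0:199) / 200
  x <- 0.1 + 0.5 * t + 3 * t^2
  sm <- kalman_smooth(x, 200, kalman_config("ca", q = 10, r = 1e-8))
  expect_lt(max(abs(sm$x[10:200] - x[10:200])), 1e-3)
  expect_error(kalman_config("cv", q = -1), "positive")
})

test_that("tune_kalman honours degenerate grids and tie-breaks", {
  set.seed(53)
  y <- sin(2 * pi * (0:199) / 100) + stats::rnorm(200, sd = 0.05)
  one <- tune_kalman(y, 200, q_grid = 7, r_grid = 3e-3, folds = 5, seed = 1)
  expect_equal(one$q, 7)
  expect_equal(one$r, 3e-3)
  expect_error(tune_kalman(y[1:4], 200, 1, 1, folds = 10), "fold count")
  expect_error(tune_kalman(y, 200, numeric(0), 1), "empty")

  # duplicated grid values produce exact ties; lower q then lower r wins
  dup <- tune_kalman(y, 200, q_grid = c(7, 7), r_grid = c(3e-3, 3e-3),
                     folds = 5, seed = 1)
  expect_equal(dup$q, 7)
  expect_equal(dup$r, 3e-3)
  expect_equal(nrow(attr(dup, "scores")), 4)
})
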