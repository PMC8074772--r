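#' @title Trajectory denoising
#' @description The two treatments compared by the pipeline: a zero-lag
#'   (dual-pass) 4th-order Butterworth low-pass filter with
#'   autocorrelation-based cutoff selection, and a fixed-interval
#'   Rauch-Tung-Striebel Kalman smoother with grid-search/cross-validated
#'   hyperparameters. Both are applied identically to every 3D coordinate
#'   channel before centre-of-mass computation.
#' @name smoothing
NULL

#' Zero-lag Butterworth low-pass filter
#'
#' 4th-order Butterworth applied forward and backward (zero phase).
#' Ends are handled by odd-reflection padding with the endpoint value
#' subtracted before filtering, which removes the step transient of the
#' zero initial filter state. No cutoff correction is applied for the
#' dual pass: `cutoff` is the per-pass design cutoff.
#'
#' @param x Numeric series sampled uniformly at `rate` Hz; must be finite
#'   (interpolate gaps upstream).
#' @param cutoff Cutoff frequency in Hz (0 < cutoff < rate/2).
#' @param rate Sampling rate in Hz.
#' @param order Filter order per pass (default 4).
#' @return Filtered series, same length as `x`.
#' @export
butterworth_lowpass <- function(x, cutoff, rate, order = 4L) {
  x <- as.numeric(x)
  if (anyNA(x) || any(!is.finite(x)))
    stop("signal contains NA/non-finite values; interpolate gaps before filtering")
  if (!(cutoff > 0 && cutoff < rate / 2))
    stop("cutoff must lie in (0, rate/2)")
  n <- length(x)
  if (n <= 3L * order)
    stop("signal too short for the requested filter order")
  bf <- signal::butter(order, cutoff / (rate / 2), type = "low")
  p <- min(n - 1L, 2L * order * ceiling(rate / cutoff))
  xp <- c(2 * x[1L] - x[(p + 1L):2L], x, 2 * x[n] - x[(n - 1L):(n - p)])
  run <- function(s) {
    s0 <- s[1L]
    as.numeric(signal::filter(bf, s - s0)) + s0
  }
  y <- rev(run(rev(run(xp))))
  y[(p + 1L):(p + n)]
}

#' Select a Butterworth cutoff from residual autocorrelation
#'
#' For each candidate cutoff the residual (raw minus filtered) is scored
#' by how far its normalized autocorrelation at lags 1..`lags` deviates
#' from the white-noise ideal of zero (sum of squared autocorrelations);
#' the cutoff minimizing the score wins. An optimally chosen cutoff
#' leaves behind a residual that looks like white noise. Residuals with
#' variance below `1e-12` of the signal variance carry no whiteness
#' information and score 0; exact ties resolve to the lowest cutoff.
#'
#' @param x Numeric series (at least ~1 s of samples).
#' @param rate Sampling rate in Hz.
#' @param cutoffs Candidate cutoff grid in Hz (default 2..30 Hz, 1 Hz
#'   step, clipped below Nyquist).
#' @param lags Number of autocorrelation lags scored (default 20).
#' @return The selected cutoff in Hz.
#' @export
select_cutoff_autocorrelation <- function(x, rate, cutoffs = 2:30,
                                          lags = 20L) {
  if (!length(cutoffs)) stop("empty cutoff grid")
  cutoffs <- sort(cutoffs[cutoffs > 0 & cutoffs < rate / 2])
  if (!length(cutoffs)) stop("no candidate cutoff below the Nyquist frequency")
  vx <- stats::var(x)
  scores <- vapply(cutoffs, function(fc) {
    r <- x - butterworth_lowpass(x, fc, rate)
    if (stats::var(r) < 1e-12 * max(vx, .Machine$double.eps)) return(0)
    ac <- stats::acf(r, lag.max = lags, plot = FALSE,
                     demean = TRUE)$acf[-1L]
    sum(ac^2)
  }, numeric(1))
  cutoffs[which.min(scores)]   # which.min takes the first (lowest) on ties
}

#' Kalman smoother configuration
#'
#' @param model State model: `"cv"` (constant velocity with white-noise
#'   acceleration) or `"ca"` (constant acceleration with white-noise
#'   jerk).
#' @param q Transition (process) noise intensity, units of the
#'   highest-order state squared per second (> 0).
#' @param r Measurement noise variance in metres squared (> 0).
#' @param p0 Initial state covariance scale (diagonal).
#' @return Object of class `kalman_config`.
#' @export
kalman_config <- function(model = c("cv", "ca"), q = 20, r = 2e-4,
                          p0 = 100) {
  model <- match.arg(model)
  if (!(q > 0) || !(r > 0)) stop("q and r must be positive")
  structure(list(model = model, q = q, r = r, p0 = p0),
            class = "kalman_config")
}

kalman_matrices <- function(model, dt, q) {
  if (model == "cv") {
    F <- matrix(c(1, 0, dt, 1), 2L, 2L)
    Q <- q * matrix(c(dt^3 / 3, dt^2 / 2, dt^2 / 2, dt), 2L, 2L)
  } else {
    F <- matrix(c(1, 0, 0, dt, 1, 0, dt^2 / 2, dt, 1), 3L, 3L)
    Q <- q * matrix(c(dt^5 / 20, dt^4 / 8, dt^3 / 6,
                      dt^4 / 8, dt^3 / 3, dt^2 / 2,
                      dt^3 / 6, dt^2 / 2, dt), 3L, 3L)
  }
  list(F = F, Q = Q)
}

# Reference (single-channel, any state dimension) RTS smoother.
# y may contain NA: the measurement update is skipped there.
kalman_smooth_ref <- function(y, rate, config) {
  dt <- 1 / rate
  mats <- kalman_matrices(config$model, dt, config$q)
  F <- mats$F
  Q <- mats$Q
  m <- nrow(F)
  H <- matrix(c(1, rep(0, m - 1L)), 1L, m)
  r <- config$r
  n <- length(y)
  first <- which(!is.na(y))[1L]
  if (is.na(first)) stop("series has no observations")
  x <- matrix(0, m, 1L)
  x[1L] <- y[first]
  P <- diag(config$p0, m)
  xf <- matrix(NA_real_, m, n)
  Pf <- array(NA_real_, c(m, m, n))
  xp <- matrix(NA_real_, m, n)
  Pp <- array(NA_real_, c(m, m, n))
  for (k in seq_len(n)) {
    if (k > 1L) {
      x <- F %*% x
      P <- F %*% P %*% t(F) + Q
    }
    xp[, k] <- x
    Pp[, , k] <- P
    if (!is.na(y[k])) {
      S <- as.numeric(H %*% P %*% t(H)) + r
      K <- (P %*% t(H)) / S
      x <- x + K * as.numeric(y[k] - H %*% x)
      P <- P - K %*% (H %*% P)
    }
    xf[, k] <- x
    Pf[, , k] <- P
  }
  xs <- xf
  Ps <- Pf
  for (k in (n - 1L):1L) {
    C <- Pf[, , k] %*% t(F) %*% solve(Pp[, , k + 1L])
    xs[, k] <- xf[, k] + C %*% (xs[, k + 1L] - xp[, k + 1L])
    Ps[, , k] <- Pf[, , k] + C %*% (Ps[, , k + 1L] - Pp[, , k + 1L]) %*% t(C)
  }
  list(x = xs[1L, ], var = Ps[1L, 1L, ],
       state = xs, filtered = xf[1L, ], filtered_var = Pf[1L, 1L, ])
}

# Fast constant-velocity RTS smoother, vectorized over the columns of Y
# (n x C matrix, NA = missing measurement). Identical output to
# kalman_smooth_ref run per column with model = "cv".
kalman_smooth_cv_mat <- function(Y, rate, config) {
  Y <- as.matrix(Y)
  n <- nrow(Y)
  C <- ncol(Y)
  dt <- 1 / rate
  q <- config$q
  r <- config$r
  Q11 <- q * dt^3 / 3
  Q12 <- q * dt^2 / 2
  Q22 <- q * dt
  # initial state: first observation per channel, zero velocity
  x1 <- numeric(C)
  for (j in seq_len(C)) {
    f <- which(!is.na(Y[, j]))[1L]
    if (is.na(f)) stop("series has no observations")
    x1[j] <- Y[f, j]
  }
  x2 <- numeric(C)
  P11 <- rep(config$p0, C)
  P12 <- numeric(C)
  P22 <- rep(config$p0, C)
  Xf1 <- Xf2 <- Pf11 <- Pf12 <- Pf22 <- matrix(0, n, C)
  Xp1 <- Xp2 <- Pp11 <- Pp12 <- Pp22 <- matrix(0, n, C)
  for (k in seq_len(n)) {
    if (k > 1L) {
      x1 <- x1 + dt * x2
      P11 <- P11 + 2 * dt * P12 + dt^2 * P22 + Q11
      P12 <- P12 + dt * P22 + Q12
      P22 <- P22 + Q22
    }
    Xp1[k, ] <- x1; Xp2[k, ] <- x2
    Pp11[k, ] <- P11; Pp12[k, ] <- P12; Pp22[k, ] <- P22
    obs <- !is.na(Y[k, ])
    if (any(obs)) {
      S <- P11[obs] + r
      K1 <- P11[obs] / S
      K2 <- P12[obs] / S
      innov <- Y[k, obs] - x1[obs]
      x1[obs] <- x1[obs] + K1 * innov
      x2[obs] <- x2[obs] + K2 * innov
      nP11 <- (1 - K1) * P11[obs]
      nP12 <- (1 - K1) * P12[obs]
      nP22 <- P22[obs] - K2 * P12[obs]
      P11[obs] <- nP11; P12[obs] <- nP12; P22[obs] <- nP22
    }
    Xf1[k, ] <- x1; Xf2[k, ] <- x2
    Pf11[k, ] <- P11; Pf12[k, ] <- P12; Pf22[k, ] <- P22
  }
  # backward RTS pass; C_k = Pf F' inv(Pp_{k+1}) with 2x2 algebra
  Xs1 <- Xf1; Xs2 <- Xf2
  Ps11 <- Pf11; Ps12 <- Pf12; Ps22 <- Pf22
  for (k in (n - 1L):1L) {
    # A = Pf F' : F = [1 dt; 0 1] so A = [P11 + dt P12, P12; P12 + dt P22, P22]
    A11 <- Pf11[k, ] + dt * Pf12[k, ]
    A12 <- Pf12[k, ]
    A21 <- Pf12[k, ] + dt * Pf22[k, ]
    A22 <- Pf22[k, ]
    det <- Pp11[k + 1L, ] * Pp22[k + 1L, ] - Pp12[k + 1L, ]^2
    I11 <- Pp22[k + 1L, ] / det
    I12 <- -Pp12[k + 1L, ] / det
    I22 <- Pp11[k + 1L, ] / det
    C11 <- A11 * I11 + A12 * I12
    C12 <- A11 * I12 + A12 * I22
    C21 <- A21 * I11 + A22 * I12
    C22 <- A21 * I12 + A22 * I22
    d1 <- Xs1[k + 1L, ] - Xp1[k + 1L, ]
    d2 <- Xs2[k + 1L, ] - Xp2[k + 1L, ]
    Xs1[k, ] <- Xf1[k, ] + C11 * d1 + C12 * d2
    Xs2[k, ] <- Xf2[k, ] + C21 * d1 + C22 * d2
    D11 <- Ps11[k + 1L, ] - Pp11[k + 1L, ]
    D12 <- Ps12[k + 1L, ] - Pp12[k + 1L, ]
    D22 <- Ps22[k + 1L, ] - Pp22[k + 1L, ]
    E11 <- C11 * D11 + C12 * D12
    E12 <- C11 * D12 + C12 * D22
    E21 <- C21 * D11 + C22 * D12
    E22 <- C21 * D12 + C22 * D22
    Ps11[k, ] <- Pf11[k, ] + E11 * C11 + E12 * C12
    Ps12[k, ] <- Pf12[k, ] + E11 * C21 + E12 * C22
    Ps22[k, ] <- Pf22[k, ] + E21 * C21 + E22 * C22
  }
  list(x = Xs1, var = Ps11, velocity = Xs2,
       filtered = Xf1, filtered_var = Pf11)
}

#' Fixed-interval Kalman (RTS) smoother
#'
#' Forward Kalman filter followed by a backward Rauch-Tung-Striebel
#' recursion, giving the optimal state estimate using the whole record.
#' Missing samples (`NA`) are supported natively: the measurement update
#' is skipped at gaps, so reconstruction failures need no interpolation.
#'
#' @param x Numeric series (may contain `NA` gaps) sampled at `rate` Hz.
#' @param rate Sampling rate in Hz.
#' @param config A [kalman_config()].
#' @return Object of class `kalman_smooth` with elements `x` (smoothed
#'   position, same length as input), `var` (posterior position
#'   variance), `velocity` (smoothed velocity state), `filtered` and
#'   `filtered_var` (forward-pass position and variance).
#' @export
kalman_smooth <- function(x, rate, config = kalman_config()) {
  if (!inherits(config, "kalman_config")) stop("config must be a kalman_config")
  if (config$model == "cv") {
    out <- kalman_smooth_cv_mat(matrix(as.numeric(x), ncol = 1L), rate, config)
    res <- list(x = out$x[, 1L], var = out$var[, 1L],
                velocity = out$velocity[, 1L],
                filtered = out$filtered[, 1L],
                filtered_var = out$filtered_var[, 1L])
  } else {
    out <- kalman_smooth_ref(as.numeric(x), rate, config)
    res <- list(x = out$x, var = out$var, velocity = out$state[2L, ],
                filtered = out$filtered, filtered_var = out$filtered_var)
  }
  structure(res, class = "kalman_smooth")
}

#' Tune Kalman smoother hyperparameters by cross-validated grid search
#'
#' For every `(q, r)` pair on the grid, runs k-fold cross-validation in
#' which the held-out samples (every k-th sample, fold offsets shuffled
#' from `seed`) are masked as missing, the smoother is run, and the
#' prediction error at the masked samples is scored by RMSE, pooled over
#' all supplied series. Returns the arg-min configuration; ties resolve
#' to the lower `q`, then the lower `r`.
#'
#' @param signals A numeric vector or a list of numeric series.
#' @param rate Sampling rate in Hz.
#' @param q_grid,r_grid Positive candidate grids.
#' @param folds Number of CV folds (default 5).
#' @param seed Integer seed controlling the fold-offset shuffle.
#' @param model State model passed to [kalman_config()].
#' @return The selected [kalman_config()], with the score table in
#'   attribute `"scores"`.
#' @export
tune_kalman <- function(signals, rate, q_grid, r_grid, folds = 5L,
                        seed = 1L, model = "cv") {
  if (!length(q_grid) || !length(r_grid)) stop("empty hyperparameter grid")
  if (is.numeric(signals)) signals <- list(signals)
  nmin <- min(vapply(signals, length, integer(1)))
  if (folds > nmin) stop("fold count exceeds series length")
  q_grid <- sort(q_grid)
  r_grid <- sort(r_grid)
  offsets <- with_local_seed(seed, sample.int(folds))
  grid <- expand.grid(q = q_grid, r = r_grid)
  sse <- numeric(nrow(grid))
  nobs <- 0L
  for (s in signals) {
    n <- length(s)
    for (f in seq_len(folds)) {
      mask <- seq(offsets[f], n, by = folds)
      mask <- mask[!is.na(s[mask])]
      if (!length(mask)) next
      ymask <- s
      ymask[mask] <- NA
      for (g in seq_len(nrow(grid))) {
        cfg <- kalman_config(model, q = grid$q[g], r = grid$r[g])
        sm <- kalman_smooth(ymask, rate, cfg)
        sse[g] <- sse[g] + sum((sm$x[mask] - s[mask])^2)
      }
      nobs <- nobs + length(mask)
    }
  }
  rmse <- sqrt(sse / nobs)
  ties <- which(rmse == min(rmse))
  best <- ties[order(grid$q[ties], grid$r[ties])][1L]  # lower q, then lower r
  cfg <- kalman_config(model, q = grid$q[best], r = grid$r[best])
  attr(cfg, "scores") <- cbind(grid, rmse = rmse)
  cfg
}
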