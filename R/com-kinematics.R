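#' de Leva segment inertial parameters mapped onto body_25 landmarks
#'
#' Sex-specific segment mass fractions and longitudinal segment-CoM
#' position ratios (measured from the proximal endpoint) after de Leva
#' (1996, J. Biomech. 29:1223-1230, adjusted Zatsiorsky-Seluyanov
#' parameters), attached to body_25 keypoints by the package's documented
#' convention: the trunk spans Neck to MidHip, the head Neck to Nose,
#' hands are point masses at the wrists and the foot spans Heel to
#' BigToe. body_25 offers no vertex, suprasternale or mid-hand landmark,
#' so this mapping is an approximation, not a reproduction of any
#' marker-based model. Mass fractions are renormalised to sum exactly
#' to 1.
#'
#' @param sex `"male"` or `"female"`.
#' @return Data frame with columns `segment`, `mass_fraction`,
#'   `com_ratio`, `proximal`, `distal` (1-based body_25 indices).
#' @export
de_leva_parameters <- function(sex = c("male", "female")) {
  sex <- match.arg(sex)
  kp <- function(name) match(name, body25_names())
  seg <- function(name, prox, dist, mf_m, cr_m, mf_f, cr_f) {
    data.frame(segment = name,
               mass_fraction = if (sex == "male") mf_m else mf_f,
               com_ratio = if (sex == "male") cr_m else cr_f,
               proximal = kp(prox), distal = kp(dist))
  }
  tab <- rbind(
    seg("head",        "Neck",      "Nose",      0.0694, 0.5002, 0.0668, 0.4841),
    seg("trunk",       "Neck",      "MidHip",    0.4346, 0.4486, 0.4257, 0.4964),
    seg("upper_arm_r", "RShoulder", "RElbow",    0.0271, 0.5772, 0.0255, 0.5754),
    seg("upper_arm_l", "LShoulder", "LElbow",    0.0271, 0.5772, 0.0255, 0.5754),
    seg("forearm_r",   "RElbow",    "RWrist",    0.0162, 0.4574, 0.0138, 0.4559),
    seg("forearm_l",   "LElbow",    "LWrist",    0.0162, 0.4574, 0.0138, 0.4559),
    seg("hand_r",      "RWrist",    "RWrist",    0.0061, 0,      0.0056, 0),
    seg("hand_l",      "LWrist",    "LWrist",    0.0061, 0,      0.0056, 0),
    seg("thigh_r",     "RHip",      "RKnee",     0.1416, 0.4095, 0.1478, 0.3612),
    seg("thigh_l",     "LHip",      "LKnee",     0.1416, 0.4095, 0.1478, 0.3612),
    seg("shank_r",     "RKnee",     "RAnkle",    0.0433, 0.4459, 0.0481, 0.4416),
    seg("shank_l",     "LKnee",     "LAnkle",    0.0433, 0.4459, 0.0481, 0.4416),
    seg("foot_r",      "RHeel",     "RBigToe",   0.0137, 0.4415, 0.0129, 0.4014),
    seg("foot_l",      "LHeel",     "LBigToe",   0.0137, 0.4415, 0.0129, 0.4014))
  tab$mass_fraction <- tab$mass_fraction / sum(tab$mass_fraction)
  tab
}

#' Whole-body centre of mass from 3D keypoints
#'
#' `CoM = sum_s massfrac_s * (proximal_s + ratio_s * (distal_s -
#' proximal_s))` over the segment table. Frames in which any required
#' segment endpoint is missing yield `NA` (the gap propagates), unless
#' `mirror_missing = TRUE`, in which case a missing limb joint is
#' replaced by its contralateral counterpart reflected across the
#' sagittal plane through MidHip (normal along the hip axis) before the
#' weighted sum.
#'
#' @param skeleton Either a 25 x 3 matrix (one frame) or an
#'   `n x 25 x 3` array of 3D keypoints in metres; missing joints `NA`.
#' @param params Segment table from [de_leva_parameters()].
#' @param mirror_missing Contralateral mirroring fallback (default off).
#' @return Length-3 CoM (one frame) or `n x 3` matrix.
#' @export
com_from_keypoints <- function(skeleton, params = de_leva_parameters("male"),
                               mirror_missing = FALSE) {
  single <- length(dim(skeleton)) == 2L
  if (single) skeleton <- array(skeleton, c(1L, dim(skeleton)))
  n <- dim(skeleton)[1L]
  if (dim(skeleton)[2L] != 25L || dim(skeleton)[3L] != 3L)
    stop("skeleton must be n x 25 x 3")
  if (mirror_missing) skeleton <- mirror_missing_joints(skeleton)
  com <- matrix(0, n, 3L)
  for (s in seq_len(nrow(params))) {
    P <- skeleton[, params$proximal[s], , drop = FALSE]
    D <- skeleton[, params$distal[s], , drop = FALSE]
    dim(P) <- c(n, 3L)
    dim(D) <- c(n, 3L)
    com <- com + params$mass_fraction[s] * (P + params$com_ratio[s] * (D - P))
  }
  if (single) as.numeric(com[1L, ]) else com
}

# Replace NA limb joints by the contralateral joint reflected across the
# sagittal plane through MidHip with normal along the LHip-RHip axis.
mirror_missing_joints <- function(skeleton) {
  nm <- body25_names()
  left <- c("LShoulder", "LElbow", "LWrist", "LHip", "LKnee", "LAnkle",
            "LBigToe", "LSmallToe", "LHeel")
  right <- sub("^L", "R", left)
  li <- match(left, nm); ri <- match(right, nm)
  mh <- match("MidHip", nm); lh <- match("LHip", nm); rh <- match("RHip", nm)
  n <- dim(skeleton)[1L]
  for (f in seq_len(n)) {
    axis <- skeleton[f, lh, ] - skeleton[f, rh, ]
    origin <- skeleton[f, mh, ]
    if (anyNA(axis) || anyNA(origin)) next
    nrm <- sqrt(sum(axis^2))
    if (nrm < 1e-9) next
    u <- axis / nrm
    reflect <- function(p) p - 2 * sum((p - origin) * u) * u
    for (k in seq_along(li)) {
      if (anyNA(skeleton[f, li[k], ]) && !anyNA(skeleton[f, ri[k], ]))
        skeleton[f, li[k], ] <- reflect(skeleton[f, ri[k], ])
      if (anyNA(skeleton[f, ri[k], ]) && !anyNA(skeleton[f, li[k], ]))
        skeleton[f, ri[k], ] <- reflect(skeleton[f, li[k], ])
    }
  }
  skeleton
}

#' Central-difference velocity of a uniformly sampled series
#'
#' Interior samples use the second-order central stencil
#' `v_i = (x_{i+1} - x_{i-1}) * rate / 2`; the two endpoints use first-
#' order one-sided differences and are flagged in the `"one_sided"`
#' attribute. A gap (`NA`) anywhere in a stencil leaves the velocity
#' undefined there.
#'
#' @param x Numeric vector or n x k matrix of positions.
#' @param rate Sampling rate in Hz.
#' @return Velocities, same shape as `x`, with attribute `"one_sided"`
#'   marking the endpoint rows.
#' @export
central_difference_velocity <- function(x, rate) {
  vec <- is.null(dim(x))
  X <- as.matrix(x)
  n <- nrow(X)
  if (n < 3L) stop("need at least 3 samples")
  V <- matrix(NA_real_, n, ncol(X))
  V[2:(n - 1L), ] <- (X[3:n, , drop = FALSE] - X[1:(n - 2L), , drop = FALSE]) *
    rate / 2
  V[1L, ] <- (X[2L, ] - X[1L, ]) * rate
  V[n, ] <- (X[n, ] - X[n - 1L, ]) * rate
  if (vec) V <- as.numeric(V)
  attr(V, "one_sided") <- c(1L, n)
  V
}

#' Flight-phase gravity validity check
#'
#' Fits a second-order polynomial to the vertical CoM trajectory over an
#' airborne window and returns the (constant) second derivative of the
#' fitted curve, for comparison against the expected -9.81 m/s^2. A CoM
#' model that does not recover gravitational acceleration in flight is
#' suspect.
#'
#' @param z Vertical CoM series in metres.
#' @param rate Sampling rate in Hz.
#' @param window Integer sample range of the flight phase (default: the
#'   whole series); at least 5 samples.
#' @return Fitted vertical acceleration in m/s^2 (scalar), with the
#'   quadratic fit coefficients in attribute `"coefficients"`.
#' @export
flight_phase_gravity_check <- function(z, rate, window = seq_along(z)) {
  window <- as.integer(window)
  if (length(window) < 5L) stop("flight window must span at least 5 samples")
  zz <- z[window]
  if (anyNA(zz)) stop("flight window contains gaps")
  t <- (window - window[1L]) / rate
  fit <- stats::lm(zz ~ t + I(t^2))
  acc <- 2 * unname(stats::coef(fit)[3L])
  attr(acc, "coefficients") <- unname(stats::coef(fit))
  acc
}
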