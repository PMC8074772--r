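#' @title Synthetic multi-camera scene generator
#' @description Generates ground-truthed multi-camera keypoint data so
#'   every pipeline stage is testable without any capture hardware: a
#'   ring of synchronized machine-vision cameras (default nine, 1920x1080,
#'   frame-locked at 200 Hz) observing an articulated 25-keypoint body
#'   performing gait-like motion, rendered to per-camera 2D detections
#'   with the characteristic noise modes of CNN pose estimators --
#'   Gaussian keypoint jitter, gross outlier detections, contralateral
#'   limb switching and missing keypoints.
#' @name synthetic_scene
NULL

#' Standard gravitational acceleration used by the simulator (m/s^2)
#' @export
STANDARD_GRAVITY <- 9.81

#' Scene configuration
#'
#' @param n_cameras Number of cameras on the rig ring (default 9, >= 2).
#' @param ring_radius Ring radius in metres (default 8).
#' @param camera_height Camera height in metres (default 2).
#' @param image_width,image_height Sensor size in pixels (default
#'   1920 x 1080).
#' @param focal_px Focal length in pixels (default 1000, a ~6 mm lens
#'   with ~90 degree horizontal field of view at this resolution).
#' @param rate Frame-locked sampling rate in Hz (default 200).
#' @param duration Capture duration in seconds (default 1.5).
#' @param n_people Number of people in the scene (default 1).
#' @param profile Motion profile: `"sprint"` (forward velocity ramp with
#'   oscillating limbs), `"push"` (crouched, pitched torso), `"ballistic"`
#'   (rigid pose on a projectile trajectory) or `"static"`.
#' @param launch_velocity Initial vertical velocity for the ballistic
#'   profile (m/s, default 3).
#' @param volume_centre Length-3 world point the cameras aim at.
#' @param distortion_k1 Mild radial distortion applied to every camera
#'   (default -0.05).
#' @param sex Segment-parameter table used for the ground-truth CoM.
#' @param seed Integer seed; all randomness in the scene flows from it.
#' @return Object of class `scene_config`.
#' @export
scene_config <- function(n_cameras = 9L, ring_radius = 8, camera_height = 2,
                         image_width = 1920L, image_height = 1080L,
                         focal_px = 1000, rate = 200, duration = 1.5,
                         n_people = 1L,
                         profile = c("sprint", "push", "ballistic", "static"),
                         launch_velocity = 3,
                         volume_centre = c(5, 0, 1),
                         distortion_k1 = -0.05,
                         sex = "male", seed = 1L) {
  profile <- match.arg(profile)
  if (n_cameras < 2L) stop("need at least 2 cameras")
  if (!(rate > 0)) stop("rate must be positive")
  structure(list(n_cameras = as.integer(n_cameras),
                 ring_radius = ring_radius, camera_height = camera_height,
                 image_width = as.integer(image_width),
                 image_height = as.integer(image_height),
                 focal_px = focal_px, rate = rate, duration = duration,
                 n_people = as.integer(n_people), profile = profile,
                 launch_velocity = launch_velocity,
                 volume_centre = as.numeric(volume_centre),
                 distortion_k1 = distortion_k1,
                 sex = sex, seed = as.integer(seed)),
            class = "scene_config")
}

#' Pose-estimator noise model
#'
#' @param jitter_sd Gaussian pixel jitter SD per keypoint per frame.
#' @param outlier_prob Probability a detected keypoint is a gross
#'   outlier.
#' @param outlier_scale Outlier displacement scale in pixels (isotropic
#'   Gaussian).
#' @param swap_prob Per-frame, per-view probability that the entire left
#'   and right leg chains (hip-knee-ankle-foot) are switched.
#' @param dropout_prob Probability a keypoint goes undetected
#'   (confidence 0).
#' @param conf_range Range of the uniform confidence distribution for
#'   detected keypoints.
#' @return Object of class `noise_model`.
#' @export
noise_model <- function(jitter_sd = 3, outlier_prob = 0.02,
                        outlier_scale = 150, swap_prob = 0.05,
                        dropout_prob = 0.05, conf_range = c(0.3, 0.95)) {
  probs <- c(outlier_prob, swap_prob, dropout_prob)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  structure(list(jitter_sd = jitter_sd, outlier_prob = outlier_prob,
                 outlier_scale = outlier_scale, swap_prob = swap_prob,
                 dropout_prob = dropout_prob, conf_range = conf_range),
            class = "noise_model")
}

#' Build a synthetic camera rig
#'
#' Places `n_cameras` evenly on a ring around the volume centre, each
#' with a proper look-at rotation (image v axis pointing down) and the
#' configured mild radial distortion.
#'
#' @param config A [scene_config()].
#' @return Named list of [camera_calibration()] (`cam1`, `cam2`, ...).
#' @export
make_rig <- function(config) {
  ctr <- config$volume_centre
  angles <- seq(0, 2 * pi, length.out = config$n_cameras + 1L)[-(config$n_cameras + 1L)]
  cals <- lapply(seq_len(config$n_cameras), function(i) {
    C <- c(ctr[1L] + config$ring_radius * cos(angles[i]),
           ctr[2L] + config$ring_radius * sin(angles[i]),
           config$camera_height)
    z <- ctr - C
    z <- z / sqrt(sum(z^2))
    up <- c(0, 0, 1)
    x <- c(z[2L] * up[3L] - z[3L] * up[2L],
           z[3L] * up[1L] - z[1L] * up[3L],
           z[1L] * up[2L] - z[2L] * up[1L])       # z x up
    x <- x / sqrt(sum(x^2))
    y <- c(z[2L] * x[3L] - z[3L] * x[2L],
           z[3L] * x[1L] - z[1L] * x[3L],
           z[1L] * x[2L] - z[2L] * x[1L])         # z x x (points down)
    R <- rbind(x, y, z)
    camera_calibration(fx = config$focal_px, fy = config$focal_px,
                       cx = config$image_width / 2,
                       cy = config$image_height / 2,
                       k1 = config$distortion_k1,
                       R = R, t = as.numeric(-R %*% C),
                       image_width = config$image_width,
                       image_height = config$image_height,
                       camera_id = paste0("cam", i))
  })
  stats::setNames(cals, vapply(cals, function(x) x$camera_id, character(1)))
}

# One articulated 25-keypoint pose. All angles in radians; the world
# frame has x along the running direction and z up.
articulated_pose <- function(midhip, torso_pitch, phase,
                             leg_amp = 0.65, knee_amp = 1.0,
                             arm_amp = 0.5, lateral = 0) {
  nm <- body25_names()
  P <- matrix(NA_real_, 25L, 3L)
  rownames(P) <- nm
  thigh <- 0.44; shank <- 0.44
  torso <- 0.55; uarm <- 0.28; farm <- 0.25
  P["MidHip", ] <- midhip
  P["RHip", ] <- midhip + c(0, -0.09, -0.02)
  P["LHip", ] <- midhip + c(0, 0.09, -0.02)
  neck <- midhip + torso * c(sin(torso_pitch), 0, cos(torso_pitch))
  P["Neck", ] <- neck
  P["RShoulder", ] <- neck + c(0, -0.18, -0.03)
  P["LShoulder", ] <- neck + c(0, 0.18, -0.03)
  nose <- neck + c(0.08 + 0.10 * sin(torso_pitch), 0, 0.14 * cos(torso_pitch))
  P["Nose", ] <- nose
  P["REye", ] <- nose + c(-0.02, -0.035, 0.04)
  P["LEye", ] <- nose + c(-0.02, 0.035, 0.04)
  P["REar", ] <- nose + c(-0.08, -0.07, 0.03)
  P["LEar", ] <- nose + c(-0.08, 0.07, 0.03)
  leg <- function(hip, th, kn) {
    knee <- hip + thigh * c(sin(th), 0, -cos(th))
    ankle <- knee + shank * c(sin(th - kn), 0, -cos(th - kn))
    list(knee = knee, ankle = ankle,
         heel = ankle + c(-0.06, 0, -0.05),
         bigtoe = ankle + c(0.13, 0, -0.06),
         smalltoe = ankle + c(0.11, 0, -0.06))
  }
  thR <- leg_amp * sin(phase) + 0.15
  thL <- leg_amp * sin(phase + pi) + 0.15
  knR <- knee_amp * (1 + cos(phase + 0.7)) / 2
  knL <- knee_amp * (1 + cos(phase + pi + 0.7)) / 2
  lr <- leg(P["RHip", ], thR, knR)
  ll <- leg(P["LHip", ], thL, knL)
  P["RKnee", ] <- lr$knee; P["RAnkle", ] <- lr$ankle
  P["RHeel", ] <- lr$heel; P["RBigToe", ] <- lr$bigtoe
  P["RSmallToe", ] <- lr$smalltoe + c(0, -0.03, 0)
  P["LKnee", ] <- ll$knee; P["LAnkle", ] <- ll$ankle
  P["LHeel", ] <- ll$heel; P["LBigToe", ] <- ll$bigtoe
  P["LSmallToe", ] <- ll$smalltoe + c(0, 0.03, 0)
  arm <- function(sh, al) {
    elbow <- sh + uarm * c(sin(al), 0, -cos(al))
    wrist <- elbow + farm * c(sin(al + 1.2), 0, -cos(al + 1.2))
    list(elbow = elbow, wrist = wrist)
  }
  alR <- arm_amp * sin(phase + pi) + torso_pitch
  alL <- arm_amp * sin(phase) + torso_pitch
  ar <- arm(P["RShoulder", ], alR)
  al_ <- arm(P["LShoulder", ], alL)
  P["RElbow", ] <- ar$elbow; P["RWrist", ] <- ar$wrist
  P["LElbow", ] <- al_$elbow; P["LWrist", ] <- al_$wrist
  P[, 2L] <- P[, 2L] + lateral
  unname(P)
}

#' Simulate ground-truth articulated motion
#'
#' Produces a kinematically smooth 25-keypoint trajectory for the
#' configured profile, plus the ground-truth whole-body CoM computed with
#' the same segment table as the pipeline (self-consistent by
#' construction). Sprint: sinusoidal limb oscillation on a forward CoM
#' velocity ramp. Push: the same gait with a strongly pitched, crouched
#' torso. Ballistic: a frozen pose translated along an exact projectile
#' path (the vertical channel is exactly quadratic in time with
#' acceleration `-STANDARD_GRAVITY`). Static: a frozen standing pose.
#'
#' @param config A [scene_config()].
#' @return List with `truth` (`n x 25 x 3` array, metres), `com`
#'   (`n x 3` ground-truth CoM), `time` (seconds), `rate`, `config`.
#'   With `n_people > 1`, `truth` and `com` are lists (one per person,
#'   offset laterally and staggered in phase).
#' @export
simulate_motion <- function(config) {
  n <- round(config$rate * config$duration)
  time <- (seq_len(n) - 1L) / config$rate
  params <- de_leva_parameters(config$sex)
  one_person <- function(lat, phase0) {
    truth <- array(NA_real_, c(n, 25L, 3L))
    f_stride <- 2                      # Hz; ~4 steps/s sprinting
    for (k in seq_len(n)) {
      t <- time[k]
      pose <- switch(config$profile,
        sprint = {
          phi <- 2 * pi * f_stride * t + phase0
          mh <- c(1 + 5 * t + 1 * t^2,
                  0.02 * sin(phi / 2),
                  0.95 + 0.035 * sin(2 * phi))
          articulated_pose(mh, torso_pitch = 0.15 + 0.03 * sin(2 * phi),
                           phase = phi)
        },
        push = {
          phi <- 2 * pi * f_stride * t + phase0
          mh <- c(1 + 2.5 * t + 1.25 * t^2,
                  0.02 * sin(phi / 2),
                  0.72 + 0.02 * sin(2 * phi))
          articulated_pose(mh, torso_pitch = 1.0 + 0.05 * sin(2 * phi),
                           phase = phi, leg_amp = 0.5, arm_amp = 0.1)
        },
        ballistic = {
          base <- articulated_pose(c(4, 0, 1.0), torso_pitch = 0.15,
                                   phase = phase0)
          off <- c(2 * t,
                   0,
                   config$launch_velocity * t - STANDARD_GRAVITY * t^2 / 2)
          sweep(base, 2L, off, "+")
        },
        static = articulated_pose(c(4, 0, 0.95), torso_pitch = 0.1,
                                  phase = phase0))
      truth[k, , ] <- pose
    }
    truth[, , 2L] <- truth[, , 2L] + lat
    list(truth = truth, com = com_from_keypoints(truth, params))
  }
  if (config$n_people == 1L) {
    p <- one_person(0, 0)
    list(truth = p$truth, com = p$com, time = time, rate = config$rate,
         config = config)
  } else {
    lats <- (seq_len(config$n_people) - (config$n_people + 1) / 2) * 2
    people <- lapply(seq_len(config$n_people), function(i)
      one_person(lats[i], (i - 1L) * 1.7))
    list(truth = lapply(people, `[[`, "truth"),
         com = lapply(people, `[[`, "com"),
         time = time, rate = config$rate, config = config)
  }
}

#' Simulate a rigid two-marker calibration wand
#'
#' Moves a rigid wand of fixed inter-marker length smoothly through the
#' capture volume (Lissajous translation, steadily rotating orientation),
#' for calibration-scale validation.
#'
#' @param n_frames Number of frames (default 100).
#' @param rate Sampling rate in Hz (default 200).
#' @param length Inter-marker distance in metres (default 0.6014).
#' @param centre Volume centre the wand moves about.
#' @return List with `a`, `b` (`n x 3` marker trajectories, exactly
#'   `length` apart at every frame) and `time`.
#' @export
simulate_wand <- function(n_frames = 100L, rate = 200, length = 0.6014,
                          centre = c(5, 0, 1)) {
  t <- (seq_len(n_frames) - 1L) / rate
  A <- cbind(centre[1L] + 1.2 * sin(2 * pi * 0.5 * t),
             centre[2L] + 0.8 * sin(2 * pi * 0.3 * t + 1),
             centre[3L] + 0.4 * sin(2 * pi * 0.4 * t + 2))
  theta <- 0.7 * sin(2 * pi * 0.2 * t)
  phi <- 2 * pi * 0.25 * t
  U <- cbind(cos(theta) * cos(phi), cos(theta) * sin(phi), sin(theta))
  list(a = A, b = A + length * U, time = t)
}

#' Render ground-truth motion to noisy per-camera keypoint detections
#'
#' Projects every keypoint of every person into every camera and applies
#' the noise model in order: dropout (including keypoints projecting
#' outside the image or behind the camera), Gaussian jitter, gross
#' outliers, and contralateral leg-chain switching. Dropped keypoints get
#' confidence 0; detected ones draw confidence from the configured
#' uniform range. Fully reproducible from `seed`.
#'
#' @param motion Result of [simulate_motion()].
#' @param rig Result of [make_rig()] (or any named calibration list).
#' @param noise A [noise_model()]; default zero noise.
#' @param seed Integer seed.
#' @return Named list (by camera id) of lists of [keypoint_frame()].
#' @export
render_detections <- function(motion, rig,
                              noise = noise_model(0, 0, 0, 0, 0),
                              seed = 1L) {
  truths <- if (is.list(motion$truth)) motion$truth else list(motion$truth)
  n <- dim(truths[[1L]])[1L]
  nm <- body25_names()
  rleg <- match(c("RHip", "RKnee", "RAnkle", "RBigToe", "RSmallToe", "RHeel"), nm)
  lleg <- match(c("LHip", "LKnee", "LAnkle", "LBigToe", "LSmallToe", "LHeel"), nm)
  with_local_seed(seed, {
    out <- lapply(rig, function(cal) {
      per_person <- lapply(truths, function(truth) {
        X <- matrix(aperm(truth, c(2L, 1L, 3L)), ncol = 3L)  # (kp fastest)
        pr <- project_points(cal, X)
        U <- matrix(pr$uv[, 1L], 25L, n)
        V <- matrix(pr$uv[, 2L], 25L, n)
        front <- matrix(pr$depth > 0, 25L, n)
        inside <- front & !is.na(U) &
          U >= 0 & U <= cal$image_width & V >= 0 & V <= cal$image_height
        drop <- !inside |
          matrix(stats::runif(25L * n) < noise$dropout_prob, 25L, n)
        if (noise$jitter_sd > 0) {
          U <- U + matrix(stats::rnorm(25L * n, sd = noise$jitter_sd), 25L, n)
          V <- V + matrix(stats::rnorm(25L * n, sd = noise$jitter_sd), 25L, n)
        }
        if (noise$outlier_prob > 0) {
          hit <- matrix(stats::runif(25L * n) < noise$outlier_prob, 25L, n)
          U[hit] <- U[hit] + stats::rnorm(sum(hit), sd = noise$outlier_scale)
          V[hit] <- V[hit] + stats::rnorm(sum(hit), sd = noise$outlier_scale)
        }
        if (noise$swap_prob > 0) {
          sw <- stats::runif(n) < noise$swap_prob
          for (k in which(sw)) {
            tmpu <- U[rleg, k]; U[rleg, k] <- U[lleg, k]; U[lleg, k] <- tmpu
            tmpv <- V[rleg, k]; V[rleg, k] <- V[lleg, k]; V[lleg, k] <- tmpv
            tmpd <- drop[rleg, k]; drop[rleg, k] <- drop[lleg, k]
            drop[lleg, k] <- tmpd
          }
        }
        conf <- matrix(stats::runif(25L * n, noise$conf_range[1L],
                                    noise$conf_range[2L]), 25L, n)
        conf[drop] <- 0
        U[drop] <- 0
        V[drop] <- 0
        list(U = U, V = V, conf = conf, drop = drop)
      })
      frames <- vector("list", n)
      for (k in seq_len(n)) {
        people <- list()
        for (pp in per_person) {
          if (all(pp$drop[, k])) next   # person entirely undetected
          people[[length(people) + 1L]] <-
            cbind(pp$U[, k], pp$V[, k], pp$conf[, k])
        }
        frames[[k]] <- keypoint_frame(k - 1L, cal$camera_id, people)
      }
      frames
    })
    stats::setNames(out, names(rig))
  })
}
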