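# Shared fixture builders: everything is generated in code at test time.

# A random valid camera looking roughly at `target` from a random position
# on a sphere of radius `radius`.
random_camera <- function(target = c(0, 0, 1), radius = 5,
                          distortion = FALSE) {
  u <- stats::rnorm(3)
  u <- u / sqrt(sum(u^2))
  C <- target + radius * u
  z <- target - C
  z <- z / sqrt(sum(z^2))
  up <- c(0, 0, 1)
  if (abs(sum(z * up)) > 0.99) up <- c(0, 1, 0)
  x <- c(z[2] * up[3] - z[3] * up[2],
         z[3] * up[1] - z[1] * up[3],
         z[1] * up[2] - z[2] * up[1])
  x <- x / sqrt(sum(x^2))
  y <- c(z[2] * x[3] - z[3] * x[2],
         z[3] * x[1] - z[1] * x[3],
         z[1] * x[2] - z[2] * x[1])
  R <- rbind(x, y, z)
  camera_calibration(
    fx = stats::runif(1, 800, 1500), fy = stats::runif(1, 800, 1500),
    cx = 960, cy = 540,
    k1 = if (distortion) stats::runif(1, -0.15, 0.05) else 0,
    k2 = if (distortion) stats::runif(1, -0.02, 0.02) else 0,
    p1 = if (distortion) stats::runif(1, -0.002, 0.002) else 0,
    p2 = if (distortion) stats::runif(1, -0.002, 0.002) else 0,
    R = R, t = as.numeric(-R %*% C))
}

# A random proper rotation matrix.
random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3))
  Q <- qr.Q(qr_)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# Rays through `point` from random origins.
rays_through_point <- function(point, n, perturb = 0) {
  lapply(seq_len(n), function(i) {
    o <- point + stats::rnorm(3, sd = 3)
    d <- point - o + stats::rnorm(3, sd = perturb)
    ray3d(o, d)
  })
}

# Brute-force RANSAC oracle: enumerate every ray pair, count inliers by
# direct distance computation, refit on the best set. Independent of the
# package's vectorized internals.
ransac_oracle <- function(rays, threshold) {
  n <- length(rays)
  best <- NULL
  best_cnt <- 0
  best_rss <- Inf
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    r1 <- rays[[i]]
    r2 <- rays[[j]]
    b <- sum(r1$direction * r2$direction)
    den <- 1 - b^2
    if (den < 1e-12) next
    w0 <- r1$origin - r2$origin
    d <- sum(r1$direction * w0)
    e <- sum(r2$direction * w0)
    s <- (b * e - d) / den
    t <- (e - b * d) / den
    p <- (r1$origin + s * r1$direction + r2$origin + t * r2$direction) / 2
    dist <- vapply(rays, function(r) {
      q <- p - r$origin
      sqrt(max(sum(q^2) - sum(q * r$direction)^2, 0))
    }, numeric(1))
    inl <- dist < threshold
    rss <- sum(dist[inl]^2)
    if (sum(inl) > best_cnt || (sum(inl) == best_cnt && rss < best_rss)) {
      best_cnt <- sum(inl)
      best_rss <- rss
      best <- inl
    }
  }
  if (is.null(best) || best_cnt < 2) return(NULL)
  list(point = intersect_rays(rays[best])$point, inliers = best)
}

# Small noiseless scene shared by several tests.
noiseless_scene <- function(n_cameras = 6, duration = 0.2,
                            profile = "sprint", n_people = 1) {
  cfg <- scene_config(n_cameras = n_cameras, duration = duration,
                      profile = profile, n_people = n_people)
  rig <- make_rig(cfg)
  mot <- simulate_motion(cfg)
  det <- render_detections(mot, rig, noise_model(0, 0, 0, 0, 0), seed = 1)
  list(cfg = cfg, rig = rig, mot = mot, det = det)
}
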