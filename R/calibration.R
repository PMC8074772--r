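#' Camera calibration object
#'
#' Constructs a validated pinhole camera calibration with the standard
#' 5-coefficient radial--tangential lens distortion model. The rotation `R`
#' maps world coordinates into the camera frame (`Xc = R X + t`); with
#' identity extrinsics the camera sits at the world origin looking along +Z,
#' x to the right and y down in the image.
#'
#' @param fx,fy Focal lengths in pixels (> 0).
#' @param cx,cy Principal point in pixels.
#' @param skew Skew coefficient in pixels (default 0).
#' @param k1,k2,k3 Radial distortion coefficients (default 0).
#' @param p1,p2 Tangential distortion coefficients (default 0).
#' @param R 3x3 orthonormal world-to-camera rotation.
#' @param t Length-3 translation in metres.
#' @param image_width,image_height Sensor size in pixels.
#' @param camera_id Optional identifier string.
#' @return An object of class `camera_calibration`.
#' @export
camera_calibration <- function(fx, fy, cx, cy, skew = 0,
                               k1 = 0, k2 = 0, k3 = 0, p1 = 0, p2 = 0,
                               R = diag(3), t = c(0, 0, 0),
                               image_width = 1920L, image_height = 1080L,
                               camera_id = NA_character_) {
  R <- matrix(as.numeric(R), 3L, 3L)
  t <- as.numeric(t)
  if (length(t) != 3L) stop("translation must have length 3")
  if (!is.finite(fx) || !is.finite(fy) || fx <= 0 || fy <= 0)
    stop("focal lengths must be positive")
  ortho <- max(abs(crossprod(R) - diag(3)))
  if (ortho > 1e-6)
    stop(sprintf("rotation is not orthonormal (||R'R - I|| = %.3g)", ortho))
  if (det(R) <= 0) stop("rotation must be proper (det(R) = +1)")
  structure(
    list(fx = fx, fy = fy, cx = cx, cy = cy, skew = skew,
         k1 = k1, k2 = k2, k3 = k3, p1 = p1, p2 = p2,
         R = R, t = t,
         image_width = as.integer(image_width),
         image_height = as.integer(image_height),
         camera_id = camera_id),
    class = "camera_calibration")
}

#' @export
print.camera_calibration <- function(x, ...) {
  cat(sprintf("<camera_calibration %s: %dx%d px, f = (%.1f, %.1f), centre at (%.2f, %.2f, %.2f) m>\n",
              ifelse(is.na(x$camera_id), "?", x$camera_id),
              x$image_width, x$image_height, x$fx, x$fy,
              camera_centre(x)[1], camera_centre(x)[2], camera_centre(x)[3]))
  invisible(x)
}

#' Camera centre in world coordinates
#'
#' @param cal A `camera_calibration`.
#' @return Length-3 numeric vector, metres.
#' @export
camera_centre <- function(cal) {
  as.numeric(-crossprod(cal$R, cal$t))
}

# Apply the radial-tangential distortion polynomial to normalized
# coordinates. x, y are equal-length vectors.
distort_normalized <- function(cal, x, y) {
  r2 <- x * x + y * y
  radial <- 1 + cal$k1 * r2 + cal$k2 * r2^2 + cal$k3 * r2^3
  xd <- x * radial + 2 * cal$p1 * x * y + cal$p2 * (r2 + 2 * x * x)
  yd <- y * radial + cal$p1 * (r2 + 2 * y * y) + 2 * cal$p2 * x * y
  list(x = xd, y = yd)
}

# Invert the distortion by fixed-point iteration (convergence 1e-12 in
# normalized units; strong radial distortion at the field edge converges
# slowly, hence the generous iteration cap).
undistort_normalized <- function(cal, xd, yd, max_iter = 100L, tol = 1e-12) {
  x <- xd
  y <- yd
  if (cal$k1 == 0 && cal$k2 == 0 && cal$k3 == 0 && cal$p1 == 0 && cal$p2 == 0)
    return(list(x = x, y = y))
  for (i in seq_len(max_iter)) {
    r2 <- x * x + y * y
    radial <- 1 + cal$k1 * r2 + cal$k2 * r2^2 + cal$k3 * r2^3
    dx <- 2 * cal$p1 * x * y + cal$p2 * (r2 + 2 * x * x)
    dy <- cal$p1 * (r2 + 2 * y * y) + 2 * cal$p2 * x * y
    xn <- (xd - dx) / radial
    yn <- (yd - dy) / radial
    delta <- max(abs(xn - x), abs(yn - y))
    x <- xn
    y <- yn
    if (delta < tol) break
  }
  # re-check: pathological coefficients may not converge
  d <- distort_normalized(cal, x, y)
  if (max(abs(d$x - xd), abs(d$y - yd)) > 1e-6)
    stop("undistortion iteration did not converge (pathological distortion coefficients?)")
  list(x = x, y = y)
}

# Vectorized projection used internally: X is an n x 3 matrix of world
# points. Returns list(uv = n x 2 matrix, depth = n-vector). Points with
# non-positive depth get NA pixels (callers decide whether that is an error).
project_points <- function(cal, X) {
  X <- matrix(as.numeric(X), ncol = 3L)
  Xc <- X %*% t(cal$R) + matrix(cal$t, nrow(X), 3L, byrow = TRUE)
  depth <- Xc[, 3L]
  x <- Xc[, 1L] / depth
  y <- Xc[, 2L] / depth
  d <- distort_normalized(cal, x, y)
  u <- cal$fx * d$x + cal$skew * d$y + cal$cx
  v <- cal$fy * d$y + cal$cy
  bad <- !(depth > 0)
  u[bad] <- NA_real_
  v[bad] <- NA_real_
  list(uv = cbind(u, v), depth = depth)
}

#' Project a world point into a camera
#'
#' Pinhole projection with radial (k1--k3) and tangential (p1, p2)
#' distortion applied in normalized coordinates before the intrinsic
#' mapping.
#'
#' @param cal A `camera_calibration`.
#' @param X World point: length-3 vector or n x 3 matrix, metres.
#' @return Pixel coordinates: length-2 vector or n x 2 matrix `(u, v)`.
#' @export
project <- function(cal, X) {
  single <- is.null(dim(X))
  X <- matrix(as.numeric(X), ncol = 3L)
  pr <- project_points(cal, X)
  if (any(!(pr$depth > 0)))
    stop("point behind camera (non-positive depth)")
  if (single) as.numeric(pr$uv[1L, ]) else unname(pr$uv)
}

#' 3D ray
#'
#' @param origin Length-3 origin, metres.
#' @param direction Length-3 direction; normalized internally.
#' @return Object of class `ray3d` with unit `direction`.
#' @export
ray3d <- function(origin, direction) {
  origin <- as.numeric(origin)
  direction <- as.numeric(direction)
  nrm <- sqrt(sum(direction^2))
  if (!is.finite(nrm) || nrm < 1e-300) stop("ray direction must be non-zero")
  structure(list(origin = origin, direction = direction / nrm),
            class = "ray3d")
}

# Vectorized back-projection: uv is an n x 2 matrix of pixels. Returns a
# 3 x n matrix of unit world-frame directions (common origin = camera centre).
backproject_points <- function(cal, uv) {
  uv <- matrix(as.numeric(uv), ncol = 2L)
  yd <- (uv[, 2L] - cal$cy) / cal$fy
  xd <- (uv[, 1L] - cal$cx - cal$skew * yd) / cal$fx
  und <- undistort_normalized(cal, xd, yd)
  dirs_cam <- rbind(und$x, und$y, rep(1, length(und$x)))
  dirs <- crossprod(cal$R, dirs_cam)        # R^T d
  nrm <- sqrt(colSums(dirs^2))
  sweep(dirs, 2L, nrm, "/")
}

#' Back-project a pixel to a world-space ray
#'
#' Returns the ray from the camera centre through the undistorted
#' normalized image point, accounting for lens distortion by iterative
#' undistortion.
#'
#' @param cal A `camera_calibration`.
#' @param d Pixel point `(u, v)`.
#' @return A [ray3d()].
#' @export
backproject <- function(cal, d) {
  dirs <- backproject_points(cal, matrix(as.numeric(d), ncol = 2L))
  ray3d(camera_centre(cal), dirs[, 1L])
}
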