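#' Rigid transform
#'
#' @param rotation Orthonormal 3x3 matrix.
#' @param translation Length-3 vector, metres.
#' @param scale Scalar scale factor (1 for a rigid transform).
#' @return Object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0),
                            scale = 1) {
  rotation <- matrix(as.numeric(rotation), 3L, 3L)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-6)
    stop("rotation is not orthonormal")
  if (det(rotation) <= 0) stop("rotation must be proper")
  structure(list(rotation = rotation, translation = as.numeric(translation),
                 scale = scale),
            class = "rigid_transform")
}

#' Apply a rigid transform to points
#'
#' @param tf A [rigid_transform()].
#' @param X Length-3 vector or n x 3 matrix.
#' @return Transformed points, same shape as `X`.
#' @export
apply_transform <- function(tf, X) {
  single <- is.null(dim(X))
  X <- matrix(as.numeric(X), ncol = 3L)
  Y <- tf$scale * (X %*% t(tf$rotation)) +
    matrix(tf$translation, nrow(X), 3L, byrow = TRUE)
  if (single) as.numeric(Y[1L, ]) else Y
}

#' Least-squares rigid alignment of two point sets (Kabsch)
#'
#' Finds the rotation and translation minimizing
#' \eqn{\sum_i \| R s_i + t - t_i \|^2} over paired points. Used to align
#' the Euclidean spaces of two motion-capture systems from a marker moved
#' through the shared volume. Scale is excluded by default (both systems
#' are metrically calibrated); a similarity variant is available via
#' `allow_scale = TRUE`.
#'
#' @param source,target n x 3 matrices of paired points (n >= 3,
#'   non-collinear).
#' @param allow_scale If `TRUE`, also estimate a global scale factor.
#' @return A [rigid_transform()] mapping `source` onto `target`.
#' @export
estimate_rigid_alignment <- function(source, target, allow_scale = FALSE) {
  source <- matrix(as.numeric(source), ncol = 3L)
  target <- matrix(as.numeric(target), ncol = 3L)
  n <- nrow(source)
  if (nrow(target) != n) stop("point sets must be paired (equal length)")
  if (n < 3L) stop("need at least 3 paired points")
  cs <- colMeans(source)
  ct <- colMeans(target)
  S <- sweep(source, 2L, cs)
  T <- sweep(target, 2L, ct)
  H <- crossprod(S, T)                     # 3x3 covariance
  sv <- svd(H)
  sing <- sv$d
  if (sing[2L] < 1e-9 * max(sing[1L], 1e-300))
    stop("degenerate configuration: points are (nearly) collinear")
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  s <- 1
  if (allow_scale) {
    denom <- sum(S^2)
    s <- sum(sing * c(1, 1, d)) / denom
  }
  t <- ct - s * as.numeric(R %*% cs)
  rigid_transform(R, t, s)
}

#' Calibration scale validation from a two-marker wand
#'
#' Computes the per-frame Euclidean distance between two rigidly connected
#' markers tracked through the capture volume and compares it to the known
#' wand length, reporting the mean and SD of the signed error in
#' millimetres.
#'
#' @param traj_a,traj_b n x 3 matrices (metres), synchronized trajectories
#'   of the two wand markers.
#' @param known_distance Known inter-marker distance in metres
#'   (default 0.6014 m).
#' @return List with `mean_error_mm`, `sd_mm`, `mean_distance_mm`, `n`.
#' @export
validate_scale <- function(traj_a, traj_b, known_distance = 0.6014) {
  traj_a <- matrix(as.numeric(traj_a), ncol = 3L)
  traj_b <- matrix(as.numeric(traj_b), ncol = 3L)
  if (nrow(traj_a) != nrow(traj_b))
    stop("trajectories must have equal length")
  d <- sqrt(rowSums((traj_a - traj_b)^2))
  err_mm <- (d - known_distance) * 1000
  list(mean_error_mm = mean(err_mm),
       sd_mm = stats::sd(err_mm),
       mean_distance_mm = mean(d) * 1000,
       n = length(d))
}
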