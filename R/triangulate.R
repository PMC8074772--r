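#' Least-squares intersection of 3D rays
#'
#' Solves for the single world point minimizing the sum of squared
#' perpendicular distances to all rays (the "intersection" of the rays).
#'
#' @param rays List of at least two [ray3d()] objects.
#' @return List with `point` (length-3, metres) and `residuals`
#'   (per-ray perpendicular distance, metres).
#' @export
intersect_rays <- function(rays) {
  if (length(rays) < 2L) stop("need at least 2 rays")
  O <- vapply(rays, function(r) r$origin, numeric(3))
  D <- vapply(rays, function(r) r$direction, numeric(3))
  A <- matrix(0, 3L, 3L)
  b <- numeric(3L)
  for (i in seq_along(rays)) {
    M <- diag(3) - tcrossprod(D[, i])
    A <- A + M
    b <- b + M %*% O[, i]
  }
  ev <- eigen(A, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-9 * length(rays))
    stop("degenerate geometry: rays are (nearly) parallel")
  p <- as.numeric(solve(A, b))
  res <- ray_point_distance(O, D, p)
  list(point = p, residuals = res)
}

# Perpendicular distance from point p to each ray (O, D are 3 x n).
# Computed from the explicit residual vector: the ||q||^2 - (q.d)^2 form
# loses ~8 digits to cancellation at metre-scale offsets.
ray_point_distance <- function(O, D, p) {
  q <- p - O
  along <- colSums(q * D)
  r <- q - D * rep(along, each = 3L)
  sqrt(colSums(r * r))
}

# Closed-form midpoint of the common perpendicular of two rays.
# Returns NULL when the rays are (nearly) parallel.
two_ray_midpoint <- function(o1, d1, o2, d2, parallel_tol = 1e-12) {
  b <- sum(d1 * d2)
  denom <- 1 - b * b
  if (denom < parallel_tol) return(NULL)
  w0 <- o1 - o2
  d <- sum(d1 * w0)
  e <- sum(d2 * w0)
  s <- (b * e - d) / denom
  t <- (e - b * d) / denom
  (o1 + s * d1 + o2 + t * d2) / 2
}

#' RANSAC triangulation of a 3D feature from multiple rays
#'
#' Proposals are two-ray intersections; the consensus set is the set of
#' rays within `inlier_threshold` of a proposal, and the final position is
#' the least-squares intersection of the largest consistent set. With 8 or
#' fewer rays every pair is enumerated exhaustively; with more rays, pairs
#' are enumerated exhaustively when their number does not exceed
#' `max_iters` and sampled deterministically from `seed` otherwise.
#'
#' @param rays List of at least two [ray3d()] objects.
#' @param inlier_threshold Ray-to-point distance below which a ray is an
#'   inlier (metres). Default 0.04 m, the order of reported markerless
#'   joint-centre error.
#' @param max_iters Maximum number of pair proposals when sampling.
#' @param seed Integer seed for pair sampling (only used when sampling).
#' @return List with `ok` (logical), `point` (length-3 or `NULL` on
#'   failure), `inliers` (logical per ray), `residuals` (distances of all
#'   rays to the final point, or `NULL`).
#' @export
ransac_triangulate <- function(rays, inlier_threshold = 0.04,
                               max_iters = 100L, seed = 1L) {
  n <- length(rays)
  if (n < 2L) stop("need at least 2 rays")
  O <- vapply(rays, function(r) r$origin, numeric(3))
  D <- vapply(rays, function(r) r$direction, numeric(3))
  pairs <- utils::combn(n, 2L)
  if (n > 8L && ncol(pairs) > max_iters) {
    keep <- with_local_seed(seed, sample.int(ncol(pairs), max_iters))
    pairs <- pairs[, sort(keep), drop = FALSE]
  }
  best_count <- 0L
  best_rss <- Inf
  best_inl <- NULL
  for (j in seq_len(ncol(pairs))) {
    i1 <- pairs[1L, j]
    i2 <- pairs[2L, j]
    p <- two_ray_midpoint(O[, i1], D[, i1], O[, i2], D[, i2])
    if (is.null(p)) next
    dist <- ray_point_distance(O, D, p)
    inl <- dist < inlier_threshold
    cnt <- sum(inl)
    rss <- sum(dist[inl]^2)
    if (cnt > best_count || (cnt == best_count && rss < best_rss)) {
      best_count <- cnt
      best_rss <- rss
      best_inl <- inl
    }
  }
  if (is.null(best_inl) || best_count < 2L) {
    return(list(ok = FALSE, point = NULL, inliers = rep(FALSE, n),
                residuals = NULL))
  }
  fit <- intersect_rays(rays[best_inl])
  res <- ray_point_distance(O, D, fit$point)
  list(ok = TRUE, point = fit$point, inliers = best_inl, residuals = res)
}

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG state afterwards.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Solve the symmetric 3x3 systems A x = b for many features at once.
# a11..a33, b1..b3 are equal-length vectors of the unique entries.
# Returns a 3-column matrix; rows with near-singular A are NA.
solve_sym3 <- function(a11, a12, a13, a22, a23, a33, b1, b2, b3) {
  c11 <- a22 * a33 - a23 * a23
  c12 <- a13 * a23 - a12 * a33
  c13 <- a12 * a23 - a13 * a22
  c22 <- a11 * a33 - a13 * a13
  c23 <- a12 * a13 - a11 * a23
  c33 <- a11 * a22 - a12 * a12
  det <- a11 * c11 + a12 * c12 + a13 * c13
  bad <- !is.finite(det) | abs(det) < 1e-12
  det[bad] <- NA_real_
  x1 <- (c11 * b1 + c12 * b2 + c13 * b3) / det
  x2 <- (c12 * b1 + c22 * b2 + c23 * b3) / det
  x3 <- (c13 * b1 + c23 * b2 + c33 * b3) / det
  cbind(x1, x2, x3)
}

# Vectorized multi-feature RANSAC triangulation used by the pipeline.
#
# origins: 3 x V matrix of camera centres.
# dirs:    3 x V x N array of unit ray directions (NA where invalid).
# valid:   V x N logical.
# Returns list(points = N x 3, ok = logical N, n_inliers = integer N,
#              inliers = V x N logical).
triangulate_features <- function(origins, dirs, valid,
                                 inlier_threshold = 0.04) {
  V <- ncol(origins)
  N <- dim(dirs)[3L]
  thr2 <- inlier_threshold^2
  pairs <- utils::combn(V, 2L)
  npair <- ncol(pairs)
  counts <- matrix(0L, npair, N)
  rsums <- matrix(Inf, npair, N)
  prop <- array(NA_real_, dim = c(3L, npair, N))
  # squared distance of every camera's ray to a set of proposal points
  ray_d2 <- function(c, P) {
    q <- P - origins[, c]                     # 3 x N
    d <- dirs[, c, ]
    along <- colSums(q * d)
    r <- q - d * rep(along, each = 3L)
    d2 <- colSums(r * r)
    d2[!valid[c, ] | !is.finite(d2)] <- Inf
    d2
  }
  for (j in seq_len(npair)) {
    a <- pairs[1L, j]
    b <- pairs[2L, j]
    use <- valid[a, ] & valid[b, ]
    if (!any(use)) next
    d1 <- dirs[, a, ]
    d2 <- dirs[, b, ]
    o1 <- origins[, a]
    o2 <- origins[, b]
    bb <- colSums(d1 * d2)
    denom <- 1 - bb * bb
    w0 <- o1 - o2
    dd <- colSums(d1 * w0)
    ee <- colSums(d2 * w0)
    ok <- use & is.finite(denom) & denom > 1e-12
    s <- (bb * ee - dd) / denom
    t <- (ee - bb * dd) / denom
    P <- ((o1 + sweep(d1, 2L, s, "*")) + (o2 + sweep(d2, 2L, t, "*"))) / 2
    P[, !ok] <- NA_real_
    prop[, j, ] <- P
    cnt <- integer(N)
    rss <- numeric(N)
    for (c in seq_len(V)) {
      d2c <- ray_d2(c, P)
      inl <- d2c < thr2
      cnt <- cnt + inl
      rss <- rss + ifelse(inl, d2c, 0)
    }
    cnt[!ok] <- 0L
    counts[j, ] <- cnt
    rsums[j, ] <- ifelse(ok, rss, Inf)
  }
  # best pair per feature: max count, then min residual sum, then pair order
  best <- integer(N)
  bestc <- integer(N)
  for (j in seq_len(npair)) {
    better <- counts[j, ] > bestc |
      (counts[j, ] == bestc & best > 0L &
         rsums[j, ] < rsums[cbind(pmax(best, 1L), seq_len(N))])
    best[better] <- j
    bestc[better] <- counts[j, better]
  }
  okf <- bestc >= 2L
  inliers <- matrix(FALSE, V, N)
  # recompute the winning proposal's inlier set, grouped by winning pair
  for (j in unique(best[okf])) {
    idx <- which(best == j & okf)
    P <- prop[, j, idx, drop = FALSE]
    dim(P) <- c(3L, length(idx))
    for (c in seq_len(V)) {
      q <- P - origins[, c]
      d <- dirs[, c, idx, drop = FALSE][, 1L, ]
      along <- colSums(q * d)
      r <- q - d * rep(along, each = 3L)
      d2 <- colSums(r * r)
      d2[!valid[c, idx]] <- Inf
      inliers[c, idx] <- is.finite(d2) & d2 < thr2
    }
  }
  # final least-squares intersection over inliers, all features at once
  a11 <- a12 <- a13 <- a22 <- a23 <- a33 <- numeric(N)
  b1 <- b2 <- b3 <- numeric(N)
  for (c in seq_len(V)) {
    w <- as.numeric(inliers[c, ])
    dx <- dirs[1L, c, ]; dy <- dirs[2L, c, ]; dz <- dirs[3L, c, ]
    dx[w == 0] <- 0; dy[w == 0] <- 0; dz[w == 0] <- 0
    m11 <- w - dx * dx; m12 <- -dx * dy; m13 <- -dx * dz
    m22 <- w - dy * dy; m23 <- -dy * dz; m33 <- w - dz * dz
    o <- origins[, c]
    a11 <- a11 + m11; a12 <- a12 + m12; a13 <- a13 + m13
    a22 <- a22 + m22; a23 <- a23 + m23; a33 <- a33 + m33
    b1 <- b1 + m11 * o[1L] + m12 * o[2L] + m13 * o[3L]
    b2 <- b2 + m12 * o[1L] + m22 * o[2L] + m23 * o[3L]
    b3 <- b3 + m13 * o[1L] + m23 * o[2L] + m33 * o[3L]
  }
  pts <- solve_sym3(a11, a12, a13, a22, a23, a33, b1, b2, b3)
  okf <- okf & apply(is.finite(pts), 1L, all)
  pts[!okf, ] <- NA_real_
  list(points = pts, ok = okf, n_inliers = bestc, inliers = inliers)
}
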