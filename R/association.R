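#' @title Occupancy-map person association
#' @description Groups per-camera person detections into cross-view person
#'   sets. Each person's 2D keypoints are reduced to a single median point;
#'   the tracked volume footprint is divided into vertical columns on a
#'   ground-plane grid; each column is projected into each camera as the
#'   axis-aligned bounding box of its eight corners; a column scores
#'   `o_k = m_k / v_k` where `v_k` counts views the column is visible in
#'   and `m_k` counts views whose projected box contains a person's median
#'   point. Peaks of the score map locate people, and the median points
#'   that contributed to a peak define the cross-camera grouping.
#' @name association
NULL

#' Median point of a person's detections
#'
#' Componentwise median of the keypoints with confidence above
#' `min_confidence`.
#'
#' @param person 25 x 3 matrix `(u, v, confidence)`.
#' @param min_confidence Keypoints at or below this confidence are
#'   ignored; default 0 keeps everything detected (confidence 0 always
#'   flags a missing keypoint).
#' @return Length-2 `(u, v)` pixel point, or `NULL` if the person has no
#'   valid keypoint.
#' @export
median_point <- function(person, min_confidence = 0) {
  ok <- person[, 3L] > min_confidence & person[, 3L] > 0
  if (!any(ok)) return(NULL)
  c(stats::median(person[ok, 1L]), stats::median(person[ok, 2L]))
}

#' Ground-plane occupancy grid specification
#'
#' @param x_range,y_range Footprint extents in metres.
#' @param cell_size Grid cell edge in metres (default 0.25 m).
#' @param z_range Column height bounds in metres (default 0 to 2.2 m,
#'   covering crouched through upright poses).
#' @param min_visibility Minimum number of views a column must be visible
#'   in to participate (default 2; a 3D feature needs two rays anyway).
#' @return Object of class `occupancy_grid_spec`.
#' @export
occupancy_grid_spec <- function(x_range, y_range, cell_size = 0.25,
                                z_range = c(0, 2.2), min_visibility = 2L) {
  if (cell_size <= 0) stop("cell_size must be positive")
  xs <- seq(x_range[1L] + cell_size / 2, x_range[2L], by = cell_size)
  ys <- seq(y_range[1L] + cell_size / 2, y_range[2L], by = cell_size)
  if (!length(xs) || !length(ys)) stop("empty occupancy grid")
  structure(list(xs = xs, ys = ys, cell_size = cell_size,
                 z_range = z_range,
                 min_visibility = as.integer(min_visibility)),
            class = "occupancy_grid_spec")
}

#' Precompute per-camera column bounding boxes for an occupancy grid
#'
#' Projects the eight corners of every rectangular column into every
#' camera and keeps the smallest axis-aligned pixel bounding box, clipped
#' to the image. Columns whose corners are all behind a camera, or whose
#' box misses the image, are not visible in that view. The grid geometry
#' is static, so this is computed once and reused for every frame.
#'
#' @param spec An [occupancy_grid_spec()].
#' @param calibrations Named list of [camera_calibration()].
#' @return Object of class `occupancy_grid` carrying cell centres,
#'   per-view bounding boxes and visibility counts.
#' @export
make_occupancy_grid <- function(spec, calibrations) {
  if (length(calibrations) < 2L) stop("need at least 2 cameras")
  nx <- length(spec$xs)
  ny <- length(spec$ys)
  centres <- cbind(rep(spec$xs, times = ny), rep(spec$ys, each = nx))
  ncol_ <- nrow(centres)
  h <- spec$cell_size / 2
  corner_off <- expand.grid(dx = c(-h, h), dy = c(-h, h), dz = spec$z_range)
  boxes <- lapply(calibrations, function(cal) {
    X <- cbind(rep(centres[, 1L], each = 8L) + rep(corner_off$dx, ncol_),
               rep(centres[, 2L], each = 8L) + rep(corner_off$dy, ncol_),
               rep(corner_off$dz, ncol_))
    pr <- project_points(cal, X)
    u <- matrix(pr$uv[, 1L], nrow = 8L)
    v <- matrix(pr$uv[, 2L], nrow = 8L)
    front <- matrix(pr$depth > 0, nrow = 8L)
    any_front <- colSums(front) > 0L
    u[!front] <- NA
    v[!front] <- NA
    x0 <- pmax(suppressWarnings(apply(u, 2L, min, na.rm = TRUE)), 0)
    x1 <- pmin(suppressWarnings(apply(u, 2L, max, na.rm = TRUE)), cal$image_width)
    y0 <- pmax(suppressWarnings(apply(v, 2L, min, na.rm = TRUE)), 0)
    y1 <- pmin(suppressWarnings(apply(v, 2L, max, na.rm = TRUE)), cal$image_height)
    vis <- any_front & is.finite(x0) & is.finite(x1) & x0 < x1 & y0 < y1
    cbind(x0 = x0, x1 = x1, y0 = y0, y1 = y1, visible = as.numeric(vis))
  })
  visibility <- rowSums(vapply(boxes, function(b) b[, "visible"],
                               numeric(ncol_)))
  structure(list(spec = spec, centres = centres, nx = nx, ny = ny,
                 boxes = boxes, visibility = visibility,
                 camera_ids = names(calibrations)),
            class = "occupancy_grid")
}

#' Project one column of an occupancy grid into a camera
#'
#' Convenience wrapper around the geometry used by
#' [make_occupancy_grid()]: the axis-aligned pixel bounding box of the
#' eight projected column corners, clipped to the image.
#'
#' @param cal A [camera_calibration()].
#' @param centre Length-2 ground-plane cell centre (metres).
#' @param cell_size Cell edge (metres).
#' @param z_range Column height bounds (metres).
#' @return Named vector `(x0, x1, y0, y1)` or `NULL` when not visible.
#' @export
project_column_bbox <- function(cal, centre, cell_size = 0.25,
                                z_range = c(0, 2.2)) {
  h <- cell_size / 2
  corners <- as.matrix(expand.grid(x = centre[1L] + c(-h, h),
                                   y = centre[2L] + c(-h, h),
                                   z = z_range))
  pr <- project_points(cal, corners)
  front <- pr$depth > 0
  if (!any(front)) return(NULL)
  u <- pr$uv[front, 1L]
  v <- pr$uv[front, 2L]
  x0 <- max(min(u), 0); x1 <- min(max(u), cal$image_width)
  y0 <- max(min(v), 0); y1 <- min(max(v), cal$image_height)
  if (!(x0 < x1 && y0 < y1)) return(NULL)
  c(x0 = x0, x1 = x1, y0 = y0, y1 = y1)
}

#' Compute the occupancy map for one frame
#'
#' For each grid column counts the views whose projected column bounding
#' box contains a person's median point (`m_k`), divides by the column's
#' visibility count (`v_k`) and records which (view, person) median
#' points contributed to each column.
#'
#' @param detections Named list (by camera id, matching the grid's
#'   calibrations) of lists of 25 x 3 person keypoint matrices for one
#'   frame.
#' @param grid An [make_occupancy_grid()] result.
#' @param min_confidence Passed to [median_point()].
#' @return Object of class `occupancy_map`: scores `o` (columns excluded
#'   for low visibility carry `NA`), counts `m` and `v`, and a
#'   contributions matrix with columns `(column, view, person)`.
#' @export
compute_occupancy <- function(detections, grid, min_confidence = 0) {
  ncol_ <- nrow(grid$centres)
  m <- numeric(ncol_)
  contrib <- vector("list", length(grid$camera_ids))
  medians <- vector("list", length(grid$camera_ids))
  for (ci in seq_along(grid$camera_ids)) {
    id <- grid$camera_ids[ci]
    people <- detections[[id]]
    if (is.null(people) || !length(people)) next
    box <- grid$boxes[[ci]]
    vis <- box[, "visible"] > 0
    seen <- logical(ncol_)
    rows <- list()
    mp <- vector("list", length(people))
    for (pi in seq_along(people)) {
      p <- median_point(people[[pi]], min_confidence)
      mp[[pi]] <- p
      if (is.null(p)) next
      inside <- vis &
        p[1L] >= box[, "x0"] & p[1L] <= box[, "x1"] &
        p[2L] >= box[, "y0"] & p[2L] <= box[, "y1"]
      if (any(inside)) {
        seen <- seen | inside
        w <- which(inside)
        rows[[length(rows) + 1L]] <- cbind(w, rep(ci, length(w)),
                                           rep(pi, length(w)))
      }
    }
    m <- m + seen
    contrib[[ci]] <- if (length(rows)) do.call(rbind, rows) else NULL
    medians[[ci]] <- mp
  }
  v <- grid$visibility
  o <- ifelse(v >= grid$spec$min_visibility, m / pmax(v, 1L), NA_real_)
  contributions <- do.call(rbind, contrib[!vapply(contrib, is.null, logical(1))])
  if (is.null(contributions))
    contributions <- matrix(integer(), 0L, 3L)
  colnames(contributions) <- c("column", "view", "person")
  structure(list(grid = grid, o = o, m = m, v = v,
                 contributions = contributions, medians = medians),
            class = "occupancy_map")
}

#' Group detections across cameras from an occupancy map
#'
#' Identifies local maxima of the occupancy score above `score_threshold`,
#' suppresses non-maximum peaks within `min_separation` metres, and forms
#' one cross-camera group per surviving peak from the median points that
#' contributed to its column. A view contributes at most one detection per
#' group (the median point closest to the projected column centre wins),
#' and a detection claimed by a higher-score peak is unavailable to later
#' peaks; equal scores resolve deterministically by grid index.
#'
#' @param occ An [compute_occupancy()] result.
#' @param score_threshold Minimum peak score (default 0.5).
#' @param min_separation Minimum peak separation in metres (default 0.5).
#' @return List of groups; each has `ground` (cell centre), `score` and
#'   `members`, a data frame `(view, person)`.
#' @export
group_detections <- function(occ, score_threshold = 0.5,
                             min_separation = 0.5) {
  grid <- occ$grid
  o <- matrix(ifelse(is.na(occ$o), -Inf, occ$o), grid$nx, grid$ny)
  nx <- grid$nx
  ny <- grid$ny
  is_peak <- o >= score_threshold
  if (!any(is_peak)) return(list())
  # local maxima over the 8-neighbourhood
  for (dx in -1:1) for (dy in -1:1) {
    if (dx == 0 && dy == 0) next
    shifted <- matrix(-Inf, nx, ny)
    xs <- max(1, 1 + dx):min(nx, nx + dx)
    ys <- max(1, 1 + dy):min(ny, ny + dy)
    shifted[xs, ys] <- o[xs - dx, ys - dy]
    is_peak <- is_peak & (o >= shifted)
  }
  idx <- which(is_peak)
  if (!length(idx)) return(list())
  ord <- idx[order(-o[idx], idx)]
  kept <- integer()
  for (k in ord) {
    if (!length(kept)) {
      kept <- k
      next
    }
    d <- sqrt((grid$centres[kept, 1L] - grid$centres[k, 1L])^2 +
              (grid$centres[kept, 2L] - grid$centres[k, 2L])^2)
    if (all(d >= min_separation)) kept <- c(kept, k)
  }
  used <- numeric()                    # claimed detections, keyed view*1e6+person
  groups <- list()
  cols <- occ$contributions[, "column"]
  for (k in kept) {
    rows <- occ$contributions[cols == k, , drop = FALSE]
    if (!nrow(rows)) next
    mv <- integer()
    mp <- integer()
    for (ci in unique(rows[, "view"])) {
      cand <- rows[rows[, "view"] == ci, "person"]
      cand <- cand[!(ci * 1e6 + cand) %in% used]
      if (!length(cand)) next
      if (length(cand) > 1L) {
        box <- grid$boxes[[ci]][k, ]
        bc <- c((box["x0"] + box["x1"]) / 2, (box["y0"] + box["y1"]) / 2)
        d2 <- vapply(cand, function(pi) {
          p <- occ$medians[[ci]][[pi]]
          sum((p - bc)^2)
        }, numeric(1))
        cand <- cand[which.min(d2)]
      }
      used <- c(used, ci * 1e6 + cand)
      mv <- c(mv, ci)
      mp <- c(mp, cand)
    }
    if (!length(mv)) next
    groups[[length(groups) + 1L]] <-
      list(ground = as.numeric(grid$centres[k, ]), score = occ$o[k],
           members = data.frame(view = mv, person = mp))
  }
  groups
}

#' Dump an occupancy map to a data frame (debugging aid)
#'
#' @param occ An [compute_occupancy()] result.
#' @return Data frame with cell centre, `v`, `m` and score `o` per column.
#' @export
occupancy_as_data_frame <- function(occ) {
  data.frame(x = occ$grid$centres[, 1L], y = occ$grid$centres[, 2L],
             v = occ$v, m = occ$m, o = occ$o)
}
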