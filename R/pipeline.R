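#' Pipeline options
#'
#' Tunable parameters of the reconstruction pipeline, with defaults used
#' throughout the package.
#'
#' @param min_confidence Keypoints at or below this confidence are
#'   discarded before fusion (default 0: keep everything detected;
#'   confidence 0 always means missing).
#' @param ransac_threshold RANSAC ray-inlier distance in metres (default
#'   0.04 m, the order of reported markerless joint-centre error).
#' @param grid_x,grid_y Occupancy-grid footprint in metres.
#' @param grid_cell Occupancy cell size in metres (default 0.25).
#' @param grid_z Occupancy column height bounds (default 0 to 2.2 m).
#' @param min_visibility Minimum views per occupancy column (default 2).
#' @param score_threshold,min_separation Peak detection parameters for
#'   [group_detections()].
#' @param link_radius Max ground-plane distance (m) for frame-to-frame
#'   track linking (simple nearest-neighbour plumbing).
#' @param link_max_gap Max frame gap across which a track may be linked.
#' @param cutoff Butterworth cutoff in Hz (default 12).
#' @param select_cutoff If `TRUE`, choose the cutoff per channel with
#'   [select_cutoff_autocorrelation()] instead of using `cutoff`.
#' @param cutoff_grid Candidate grid for cutoff selection.
#' @param kalman A [kalman_config()] used for the Kalman treatment.
#' @param treatments Subset of `c("raw", "lowpass", "kalman")`.
#' @param sex Segment-parameter table for the CoM model.
#' @return List of class `pipeline_options`.
#' @export
pipeline_options <- function(min_confidence = 0, ransac_threshold = 0.04,
                             grid_x = c(-1, 12), grid_y = c(-2, 2),
                             grid_cell = 0.25, grid_z = c(0, 2.2),
                             min_visibility = 2L, score_threshold = 0.5,
                             min_separation = 0.5, link_radius = 1.0,
                             link_max_gap = 25L, cutoff = 12,
                             select_cutoff = FALSE, cutoff_grid = 2:30,
                             kalman = kalman_config(),
                             treatments = c("raw", "lowpass", "kalman"),
                             sex = "male") {
  treatments <- match.arg(treatments, c("raw", "lowpass", "kalman"),
                          several.ok = TRUE)
  structure(as.list(environment()), class = "pipeline_options")
}

#' Reconstruct 3D skeletons from multi-camera keypoint detections
#'
#' Per frame: associates person detections across views with the
#' occupancy map, links groups over time by nearest ground position, and
#' triangulates each keypoint of each tracked person by RANSAC over the
#' back-projected rays of its 2D detections.
#'
#' @param detections Named list (by camera id) of lists of
#'   [keypoint_frame()], one entry per camera, equal frame counts.
#' @param calibrations Named list of [camera_calibration()] with the same
#'   names.
#' @param options A [pipeline_options()].
#' @return List of tracks; each track has `points` (`n x 25 x 3`, `NA`
#'   where reconstruction failed), `n_inliers` (`n x 25`), `frames`
#'   (frames where the person was associated) plus a `log` of stage
#'   counts attached as an attribute on the list.
#' @export
reconstruct_skeletons <- function(detections, calibrations,
                                  options = pipeline_options()) {
  cams <- names(calibrations)
  if (!all(cams %in% names(detections)))
    stop("detections missing for cameras: ",
         paste(setdiff(cams, names(detections)), collapse = ", "))
  nf <- length(detections[[cams[1L]]])
  if (!all(vapply(detections[cams], length, integer(1)) == nf))
    stop("all cameras must supply the same number of frames")
  V <- length(cams)
  spec <- occupancy_grid_spec(options$grid_x, options$grid_y,
                              options$grid_cell, options$grid_z,
                              options$min_visibility)
  grid <- make_occupancy_grid(spec, calibrations)
  tracks <- list()   # assign: nf x V person index; ground; last_frame
  n_groups <- 0L
  n_detections <- 0L
  for (f in seq_len(nf)) {
    det <- lapply(cams, function(cid) detections[[cid]][[f]]$people)
    names(det) <- cams
    n_detections <- n_detections + sum(lengths(det))
    occ <- compute_occupancy(det, grid, options$min_confidence)
    groups <- group_detections(occ, options$score_threshold,
                               options$min_separation)
    n_groups <- n_groups + length(groups)
    claimed <- logical(length(tracks))
    for (g in groups) {
      best <- 0L
      bestd <- options$link_radius
      for (ti in seq_along(tracks)) {
        if (claimed[ti]) next
        if (f - tracks[[ti]]$last_frame > options$link_max_gap) next
        d <- sqrt(sum((tracks[[ti]]$ground - g$ground)^2))
        if (d < bestd) {
          bestd <- d
          best <- ti
        }
      }
      if (best == 0L) {
        tracks[[length(tracks) + 1L]] <-
          list(assign = matrix(NA_integer_, nf, V), ground = g$ground,
               last_frame = f)
        claimed <- c(claimed, TRUE)
        best <- length(tracks)
      } else {
        claimed[best] <- TRUE
      }
      tracks[[best]]$ground <- g$ground
      tracks[[best]]$last_frame <- f
      tracks[[best]]$assign[f, g$members$view] <- g$members$person
    }
  }
  origins <- vapply(calibrations, camera_centre, numeric(3))
  out <- lapply(tracks, function(tr) {
    N <- nf * 25L
    dirs <- array(NA_real_, c(3L, V, N))
    valid <- matrix(FALSE, V, N)
    for (ci in seq_len(V)) {
      pidx <- tr$assign[, ci]
      fw <- which(!is.na(pidx))
      if (!length(fw)) next
      KU <- matrix(NA_real_, 25L, nf)
      KV <- matrix(NA_real_, 25L, nf)
      KC <- matrix(0, 25L, nf)
      for (f in fw) {
        p <- detections[[cams[ci]]][[f]]$people[[pidx[f]]]
        KU[, f] <- p[, 1L]
        KV[, f] <- p[, 2L]
        KC[, f] <- p[, 3L]
      }
      val <- KC > options$min_confidence & KC > 0
      idx <- which(val)                 # column-major: keypoint fastest
      if (!length(idx)) next
      dirs[, ci, idx] <- backproject_points(calibrations[[ci]],
                                            cbind(KU[idx], KV[idx]))
      valid[ci, idx] <- TRUE
    }
    tri <- triangulate_features(origins, dirs, valid,
                                options$ransac_threshold)
    pts <- array(NA_real_, c(25L, nf, 3L))
    for (d in 1:3) pts[, , d] <- matrix(tri$points[, d], 25L, nf)
    list(points = aperm(pts, c(2L, 1L, 3L)),
         n_inliers = t(matrix(tri$n_inliers, 25L, nf)),
         frames = which(rowSums(!is.na(tr$assign)) > 0L))
  })
  n_rec <- sum(vapply(out, function(tr) sum(!is.na(tr$points[, , 1L])),
                      numeric(1)))
  attr(out, "log") <- list(frames = nf, detections = n_detections,
                           groups = n_groups, tracks = length(out),
                           reconstructed = n_rec,
                           gaps = length(out) * nf * 25L - n_rec)
  out
}

# Linearly interpolate interior NA runs of a vector; ends are held at the
# nearest observed value. Returns list(x, filled) where filled flags the
# interpolated samples.
interpolate_gaps <- function(x) {
  na <- is.na(x)
  if (!any(na)) return(list(x = x, filled = na))
  if (all(na)) return(list(x = x, filled = rep(FALSE, length(x))))
  idx <- which(!na)
  out <- stats::approx(idx, x[idx], xout = seq_along(x), rule = 2)$y
  list(x = out, filled = na)
}

#' Apply a denoising treatment to a 3D keypoint trajectory array
#'
#' `"raw"` returns the input; `"lowpass"` linearly interpolates gaps
#' (flagged in the `"interpolated"` attribute) then applies the zero-lag
#' Butterworth per coordinate channel; `"kalman"` runs the fixed-interval
#' smoother per channel with gaps as skipped measurement updates. Both
#' smoothing treatments process every coordinate channel identically.
#'
#' @param points `n x 25 x 3` keypoint array (`NA` = gap).
#' @param rate Sampling rate in Hz.
#' @param treatment One of `"raw"`, `"lowpass"`, `"kalman"`.
#' @param options A [pipeline_options()].
#' @return Treated array, same shape.
#' @export
apply_treatment <- function(points, rate,
                            treatment = c("raw", "lowpass", "kalman"),
                            options = pipeline_options()) {
  treatment <- match.arg(treatment)
  if (treatment == "raw") return(points)
  n <- dim(points)[1L]
  Y <- matrix(points, n, 75L)
  have <- colSums(!is.na(Y)) >= 2L
  out <- Y
  if (treatment == "lowpass") {
    filled <- matrix(FALSE, n, 75L)
    for (j in which(have)) {
      g <- interpolate_gaps(Y[, j])
      fc <- if (options$select_cutoff)
        select_cutoff_autocorrelation(g$x, rate, options$cutoff_grid)
      else options$cutoff
      out[, j] <- butterworth_lowpass(g$x, fc, rate)
      filled[, j] <- g$filled
    }
    res <- array(out, dim(points))
    attr(res, "interpolated") <- array(filled, dim(points))
    return(res)
  }
  sm <- kalman_smooth_cv_mat(Y[, have, drop = FALSE], rate, options$kalman)
  out[, have] <- sm$x
  array(out, dim(points))
}

#' Run the full centre-of-mass pipeline on in-memory detections
#'
#' Orchestrates association, triangulation, the requested denoising
#' treatments, CoM computation and central-difference velocities, and --
#' when a criterion CoM is supplied -- Bland-Altman plus regression
#' agreement for horizontal (x, the running direction) and vertical (z)
#' position and velocity. The world frame convention is z up, x along the
#' running direction.
#'
#' @param detections Named list (by camera id) of [keypoint_frame()]
#'   lists.
#' @param calibrations Matching named list of [camera_calibration()].
#' @param rate Sampling rate in Hz.
#' @param criterion_com Optional `n x 3` criterion CoM trajectory
#'   (metres) time-aligned with the frames, used for agreement analysis
#'   of the first tracked person.
#' @param options A [pipeline_options()].
#' @return Object of class `com_pipeline`: `tracks` (raw skeletons),
#'   `treatments` (per treatment: `points`, `com`, `velocity`),
#'   `agreement` (`position` and `velocity` [comparison_table()]s, or
#'   `NULL`), `log`, `rate`, `time`.
#' @export
com_pipeline <- function(detections, calibrations, rate,
                         criterion_com = NULL,
                         options = pipeline_options()) {
  tracks <- reconstruct_skeletons(detections, calibrations, options)
  log <- attr(tracks, "log")
  if (!length(tracks)) stop("association found no people to reconstruct")
  params <- de_leva_parameters(options$sex)
  pts <- tracks[[1L]]$points
  n <- dim(pts)[1L]
  time <- (seq_len(n) - 1L) / rate
  treatments <- list()
  for (tr in options$treatments) {
    tp <- apply_treatment(pts, rate, tr, options)
    com <- com_from_keypoints(tp, params)
    vel <- central_difference_velocity(com, rate)
    treatments[[tr]] <- list(points = tp, com = com, velocity = vel)
  }
  agreement <- NULL
  if (!is.null(criterion_com)) {
    criterion_com <- matrix(as.numeric(criterion_com), ncol = 3L)
    if (nrow(criterion_com) != n)
      stop("criterion CoM length does not match the reconstruction")
    crit_vel <- central_difference_velocity(criterion_com, rate)
    interior <- 2:(n - 1L)               # drop one-sided endpoint stencils
    pos_res <- list()
    vel_res <- list()
    for (tr in names(treatments)) {
      com <- treatments[[tr]]$com
      vel <- treatments[[tr]]$velocity
      pos_res[[tr]] <- list(
        horizontal = agreement_summary(com[, 1L], criterion_com[, 1L]),
        vertical = agreement_summary(com[, 3L], criterion_com[, 3L]))
      vel_res[[tr]] <- list(
        horizontal = agreement_summary(vel[interior, 1L],
                                       crit_vel[interior, 1L]),
        vertical = agreement_summary(vel[interior, 3L],
                                     crit_vel[interior, 3L]))
    }
    agreement <- list(position = comparison_table(pos_res),
                      velocity = comparison_table(vel_res))
  }
  structure(list(tracks = tracks, treatments = treatments,
                 agreement = agreement, log = log, rate = rate,
                 time = time, options = options),
            class = "com_pipeline")
}

#' @export
print.com_pipeline <- function(x, ...) {
  cat(sprintf("<com_pipeline: %d frames @ %g Hz, %d track(s), treatments: %s>\n",
              x$log$frames, x$rate, x$log$tracks,
              paste(names(x$treatments), collapse = ", ")))
  cat(sprintf("  detections in: %d; groups: %d; 3D features: %d; gaps: %d\n",
              x$log$detections, x$log$groups, x$log$reconstructed,
              x$log$gaps))
  invisible(x)
}

#' @export
summary.com_pipeline <- function(object, ...) {
  print(object)
  if (!is.null(object$agreement)) {
    cat("\nCoM position agreement (markerless - criterion):\n")
    print(as.data.frame(object$agreement$position), digits = 3)
    cat("\nCoM velocity agreement (markerless - criterion):\n")
    print(as.data.frame(object$agreement$velocity), digits = 3)
  }
  invisible(object)
}

#' @export
plot.com_pipeline <- function(x, component = c("horizontal", "vertical"),
                              what = c("velocity", "com"), ...) {
  component <- match.arg(component)
  what <- match.arg(what)
  dim_idx <- if (component == "horizontal") 1L else 3L
  cols <- c(raw = "grey50", lowpass = "red3", kalman = "blue3")
  ylab <- if (what == "velocity")
    sprintf("CoM %s velocity (m/s)", component)
  else sprintf("CoM %s position (m)", component)
  ys <- lapply(x$treatments, function(tr) tr[[what]][, dim_idx])
  rng <- range(unlist(ys), na.rm = TRUE)
  graphics::plot(NA, xlim = range(x$time), ylim = rng,
                 xlab = "time (s)", ylab = ylab, ...)
  for (tr in names(ys))
    graphics::lines(x$time, ys[[tr]], col = cols[[tr]])
  graphics::legend("topleft", legend = names(ys), col = cols[names(ys)],
                   lty = 1, bty = "n")
  invisible(x)
}

#' Run the pipeline from a configuration file or list
#'
#' File-based entry point: reads consolidated per-camera keypoint files
#' and the calibration set, runs [com_pipeline()], and writes one CoM
#' trajectory CSV per treatment, agreement CSVs when a criterion
#' trajectory is given, and a log file, into the output directory.
#'
#' @param config A YAML file path or a list with elements:
#'   `keypoints` (named camera id -> file path, or a directory of
#'   `<camera_id>.json` files), `calibration` (YAML path), `output`
#'   (directory), optional `criterion` (CSV with `com_x/com_y/com_z`),
#'   `rate` (default 200), and optional overrides for
#'   [pipeline_options()] fields under `options`.
#' @return The [com_pipeline()] object, invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  for (field in c("keypoints", "calibration", "output"))
    if (is.null(config[[field]]))
      stop(sprintf("config error: missing '%s'", field))
  if (!file.exists(config$calibration))
    stop(sprintf("config error: calibration file not found: %s",
                 config$calibration))
  calibrations <- read_calibration_set(config$calibration)
  kp <- config$keypoints
  if (length(kp) == 1L && is.null(names(kp)) && dir.exists(kp[[1L]])) {
    files <- list.files(kp[[1L]], pattern = "\\.json$", full.names = TRUE)
    kp <- stats::setNames(as.list(files),
                          sub("\\.json$", "", basename(files)))
  }
  detections <- lapply(names(kp), function(cid)
    read_keypoint_file(kp[[cid]], cid))
  names(detections) <- names(kp)
  rate <- config$rate %||% 200
  criterion <- NULL
  if (!is.null(config$criterion)) {
    tab <- read_trajectory(config$criterion, rate = rate)
    criterion <- as.matrix(tab[c("com_x", "com_y", "com_z")])
  }
  opts <- do.call(pipeline_options, config$options %||% list())
  res <- com_pipeline(detections, calibrations, rate, criterion, opts)
  dir.create(config$output, showWarnings = FALSE, recursive = TRUE)
  for (tr in names(res$treatments)) {
    com <- res$treatments[[tr]]$com
    tab <- trajectory_table(res$time,
                            data.frame(com_x = com[, 1L], com_y = com[, 2L],
                                       com_z = com[, 3L]),
                            rate, provenance = if (tr == "raw") "raw" else tr)
    write_trajectory(tab, file.path(config$output,
                                    sprintf("com_%s.csv", tr)))
  }
  if (!is.null(res$agreement)) {
    write_comparison_table(res$agreement$position,
                           file.path(config$output, "agreement_position.csv"))
    write_comparison_table(res$agreement$velocity,
                           file.path(config$output, "agreement_velocity.csv"))
  }
  writeLines(c(sprintf("frames: %d", res$log$frames),
               sprintf("detections: %d", res$log$detections),
               sprintf("groups: %d", res$log$groups),
               sprintf("tracks: %d", res$log$tracks),
               sprintf("reconstructed: %d", res$log$reconstructed),
               sprintf("gaps: %d", res$log$gaps)),
             file.path(config$output, "pipeline_log.txt"))
  invisible(res)
}
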