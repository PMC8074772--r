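#' @title Keypoint, calibration and trajectory file I/O
#' @description Readers and writers for the external artefacts the
#'   pipeline touches: OpenPose body_25 keypoint files (native one-file-
#'   per-frame layout and a consolidated per-camera file, which is the
#'   canonical layout here), a YAML camera-calibration set, and CSV
#'   trajectory tables.
#' @name io_formats
NULL

#' body_25 keypoint names
#'
#' Keypoint order of the OpenPose body_25 model: 0 Nose, 1 Neck, 2-4 right
#' arm, 5-7 left arm, 8 MidHip, 9-11 right leg, 12-14 left leg, 15-18
#' eyes/ears, 19-24 feet.
#'
#' @return Character vector of length 25 (index i names keypoint i-1).
#' @export
body25_names <- function() {
  c("Nose", "Neck",
    "RShoulder", "RElbow", "RWrist",
    "LShoulder", "LElbow", "LWrist",
    "MidHip",
    "RHip", "RKnee", "RAnkle",
    "LHip", "LKnee", "LAnkle",
    "REye", "LEye", "REar", "LEar",
    "LBigToe", "LSmallToe", "LHeel",
    "RBigToe", "RSmallToe", "RHeel")
}

#' Single-frame keypoint record
#'
#' @param frame_index Integer frame index (>= 0).
#' @param camera_id Camera identifier string.
#' @param people List of 25 x 3 matrices `(u, v, confidence)`; confidence
#'   0 flags a missing keypoint whose coordinates are ignored.
#' @return Object of class `keypoint_frame`.
#' @export
keypoint_frame <- function(frame_index, camera_id, people = list()) {
  people <- lapply(people, function(p) {
    p <- matrix(as.numeric(p), ncol = 3L)
    if (nrow(p) != 25L) stop("each person must have exactly 25 keypoints")
    colnames(p) <- c("u", "v", "confidence")
    if (any(p[, 3L] < 0 | p[, 3L] > 1)) stop("confidence must be in [0, 1]")
    p
  })
  structure(list(frame_index = as.integer(frame_index),
                 camera_id = camera_id, people = people),
            class = "keypoint_frame")
}

person_from_flat <- function(flat, where) {
  if (length(flat) != 75L)
    stop(sprintf("schema error at %s: pose_keypoints_2d has length %d, expected 75",
                 where, length(flat)))
  matrix(as.numeric(flat), ncol = 3L, byrow = TRUE,
         dimnames = list(NULL, c("u", "v", "confidence")))
}

#' Read a consolidated per-camera keypoint file
#'
#' The consolidated JSON layout holds every frame of one camera:
#' `{"camera_id": ..., "frames": [{"frame_index": ..., "people":
#' [{"pose_keypoints_2d": [75 numbers]}, ...]}, ...]}`. Each person is a
#' flat 75-value `(u, v, confidence)` array in body_25 order, as written
#' by OpenPose.
#'
#' @param path File path.
#' @param camera_id Camera identifier; defaults to the one stored in the
#'   file.
#' @return List of [keypoint_frame()] in frame-index order; person order
#'   within a frame is preserved from the file.
#' @export
read_keypoint_file <- function(path, camera_id = NULL) {
  if (!file.exists(path)) stop(sprintf("keypoint file not found: %s", path))
  doc <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e)
                    stop(sprintf("parse error in %s: %s", path, conditionMessage(e))))
  if (is.null(doc$frames)) stop(sprintf("schema error in %s: no 'frames' field", path))
  cid <- camera_id %||% doc$camera_id %||% NA_character_
  frames <- lapply(doc$frames, function(fr) {
    if (is.null(fr$frame_index))
      stop(sprintf("parse error in %s: frame record without frame_index", path))
    people <- lapply(seq_along(fr$people), function(i) {
      person_from_flat(unlist(fr$people[[i]]$pose_keypoints_2d),
                       sprintf("%s frame %s person %d", path, fr$frame_index, i))
    })
    keypoint_frame(fr$frame_index, cid, people)
  })
  idx <- vapply(frames, function(f) f$frame_index, integer(1))
  frames[order(idx)]
}

#' Write a consolidated per-camera keypoint file
#'
#' @param frames List of [keypoint_frame()] (one camera).
#' @param path Output file path.
#' @export
write_keypoint_file <- function(frames, path) {
  cid <- if (length(frames)) frames[[1L]]$camera_id else NA_character_
  doc <- list(
    camera_id = cid,
    frames = lapply(frames, function(fr) {
      list(frame_index = fr$frame_index,
           people = lapply(fr$people, function(p)
             list(pose_keypoints_2d = as.numeric(t(p)))))
    }))
  # digits = I(17): 17 significant digits, enough for exact double round-trip
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' Read a native OpenPose output directory (one JSON file per frame)
#'
#' Files are expected to match the OpenPose naming convention
#' `<prefix>_<frameindex>_keypoints.json` with the frame index parsed from
#' the file name.
#'
#' @param dir Directory containing the per-frame JSON files.
#' @param camera_id Camera identifier to stamp onto the frames.
#' @return List of [keypoint_frame()] in frame-index order.
#' @export
read_keypoint_dir <- function(dir, camera_id) {
  files <- list.files(dir, pattern = "_keypoints\\.json$", full.names = TRUE)
  if (!length(files)) stop(sprintf("no *_keypoints.json files in %s", dir))
  idx <- as.integer(sub(".*_(\\d+)_keypoints\\.json$", "\\1", basename(files)))
  if (anyNA(idx)) stop("cannot parse frame index from OpenPose file names")
  ord <- order(idx)
  frames <- lapply(ord, function(i) {
    doc <- jsonlite::fromJSON(files[i], simplifyVector = FALSE)
    people <- lapply(seq_along(doc$people), function(j)
      person_from_flat(unlist(doc$people[[j]]$pose_keypoints_2d),
                       sprintf("%s person %d", files[i], j)))
    keypoint_frame(idx[i], camera_id, people)
  })
  frames
}

#' Read a camera-calibration set
#'
#' A single YAML document with one entry per camera under `cameras:`,
#' each carrying explicit fields `id, fx, fy, cx, cy, skew, k1, k2, k3,
#' p1, p2, R` (3x3, row-major, world-to-camera), `t` (metres),
#' `image_width, image_height`. With identity extrinsics the camera is at
#' the world origin looking along +Z.
#'
#' @param path YAML file path.
#' @return Named list of [camera_calibration()] keyed by camera id.
#' @export
read_calibration_set <- function(path) {
  if (!file.exists(path)) stop(sprintf("calibration file not found: %s", path))
  doc <- yaml::read_yaml(path)
  if (is.null(doc$cameras)) stop("calibration file has no 'cameras' entry")
  cals <- lapply(doc$cameras, function(cc) {
    need <- c("id", "fx", "fy", "cx", "cy", "R", "t")
    miss <- setdiff(need, names(cc))
    if (length(miss))
      stop(sprintf("calibration entry missing fields: %s",
                   paste(miss, collapse = ", ")))
    camera_calibration(
      fx = cc$fx, fy = cc$fy, cx = cc$cx, cy = cc$cy,
      skew = cc$skew %||% 0,
      k1 = cc$k1 %||% 0, k2 = cc$k2 %||% 0, k3 = cc$k3 %||% 0,
      p1 = cc$p1 %||% 0, p2 = cc$p2 %||% 0,
      R = matrix(as.numeric(unlist(cc$R)), 3L, 3L, byrow = TRUE),
      t = as.numeric(unlist(cc$t)),
      image_width = cc$image_width %||% 1920L,
      image_height = cc$image_height %||% 1080L,
      camera_id = as.character(cc$id))
  })
  ids <- vapply(cals, function(x) x$camera_id, character(1))
  if (anyDuplicated(ids))
    stop(sprintf("duplicate camera_id in calibration set: %s",
                 ids[duplicated(ids)][1L]))
  stats::setNames(cals, ids)
}

#' Write a camera-calibration set
#'
#' @param calibrations Named list of [camera_calibration()].
#' @param path Output YAML path.
#' @export
write_calibration_set <- function(calibrations, path) {
  doc <- list(cameras = unname(lapply(calibrations, function(cal) {
    list(id = cal$camera_id,
         fx = cal$fx, fy = cal$fy, cx = cal$cx, cy = cal$cy,
         skew = cal$skew,
         k1 = cal$k1, k2 = cal$k2, k3 = cal$k3, p1 = cal$p1, p2 = cal$p2,
         R = lapply(1:3, function(i) as.numeric(cal$R[i, ])),
         t = as.numeric(cal$t),
         image_width = cal$image_width, image_height = cal$image_height)
  })))
  yaml::write_yaml(doc, path, precision = 17L)
  invisible(path)
}

#' Trajectory table
#'
#' A fixed-rate time series of 3D landmarks or derived quantities. Time is
#' seconds at a strictly fixed step `1/rate`; coordinates are metres; one
#' `<name>_x/_y/_z` column triple per landmark.
#'
#' @param time Numeric vector of sample times (seconds).
#' @param data Data frame (or matrix) of coordinate columns named
#'   `<landmark>_x`, `<landmark>_y`, `<landmark>_z`.
#' @param rate Sampling rate in Hz.
#' @param provenance One of `"raw"`, `"lowpass"`, `"kalman"`,
#'   `"criterion"`.
#' @return Object of class `trajectory_table` (a data frame with a `time`
#'   column first and attributes `rate` and `provenance`).
#' @export
trajectory_table <- function(time, data, rate,
                             provenance = c("raw", "lowpass", "kalman",
                                            "criterion")) {
  provenance <- match.arg(provenance)
  time <- as.numeric(time)
  if (length(time) > 1L) {
    dt <- diff(time)
    if (any(dt <= 0)) stop("time must be strictly increasing")
    if (max(abs(dt - 1 / rate)) > 1e-9 / rate)
      stop("time must advance at the fixed step 1/rate (gapped frames are not representable)")
  }
  df <- data.frame(time = time, as.data.frame(data), check.names = FALSE)
  structure(df, rate = rate, provenance = provenance,
            class = c("trajectory_table", "data.frame"))
}

#' Write a trajectory table to CSV
#'
#' Writes a header row (`time` plus landmark columns). `NA` values (gaps
#' in the reconstruction) are written as empty cells.
#'
#' @param table A [trajectory_table()].
#' @param path Output CSV path.
#' @export
write_trajectory <- function(table, path) {
  if (!inherits(table, "trajectory_table"))
    stop("table must be a trajectory_table")
  utils::write.csv(as.data.frame(table), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a trajectory table from CSV
#'
#' @param path CSV path written by [write_trajectory()] (or a criterion
#'   trajectory in the same layout).
#' @param rate Sampling rate in Hz; inferred from the time column when
#'   omitted.
#' @param provenance Provenance tag for the returned table.
#' @return A [trajectory_table()].
#' @export
read_trajectory <- function(path, rate = NULL, provenance = "criterion") {
  if (!file.exists(path)) stop(sprintf("trajectory file not found: %s", path))
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"time" %in% names(df)) stop("trajectory CSV must have a 'time' column")
  if (is.null(rate)) {
    if (nrow(df) < 2L) stop("cannot infer rate from a single row")
    rate <- 1 / stats::median(diff(df$time))
  }
  trajectory_table(df$time, df[setdiff(names(df), "time")], rate, provenance)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
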