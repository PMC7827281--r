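#' The 25-joint skeletal model
#'
#' Names of the 25 joints tracked by the depth sensor's skeletal stream,
#' following the sensor SDK's standard joint set: the spine chain
#' (SPINE_BASE, SPINE_MID, SPINE_SHOULDER, NECK, HEAD), the two arms
#' (SHOULDER, ELBOW, WRIST, HAND, HAND_TIP, THUMB on each side) and the two
#' legs (HIP, KNEE, ANKLE, FOOT on each side).
#'
#' @return A character vector of 25 joint identifiers.
#' @export
#' @examples
#' length(kinect_joints())
kinect_joints <- function() {
  c(
    "SPINE_BASE", "SPINE_MID", "SPINE_SHOULDER", "NECK", "HEAD",
    "SHOULDER_LEFT", "ELBOW_LEFT", "WRIST_LEFT", "HAND_LEFT",
    "HAND_TIP_LEFT", "THUMB_LEFT",
    "SHOULDER_RIGHT", "ELBOW_RIGHT", "WRIST_RIGHT", "HAND_RIGHT",
    "HAND_TIP_RIGHT", "THUMB_RIGHT",
    "HIP_LEFT", "KNEE_LEFT", "ANKLE_LEFT", "FOOT_LEFT",
    "HIP_RIGHT", "KNEE_RIGHT", "ANKLE_RIGHT", "FOOT_RIGHT"
  )
}

# Depth working range of the sensor, metres.
DEPTH_RANGE_M <- c(0.4, 4.5)

# Coordinate convention (a documented package choice; sensor documentation
# does not fix handedness or the vertical axis):
# right-handed camera space in metres, origin at the sensor, +y up,
# +z from the sensor toward the user, +x completing the right-handed triad.
# The user faces the sensor, so the user's anterior direction is -z.

check_joint <- function(joint, arg = "joint") {
  bad <- setdiff(joint, kinect_joints())
  if (length(bad) > 0) {
    abort(sprintf("unknown joint identifier(s) in `%s`: %s",
                  arg, paste(bad, collapse = ", ")),
          class = "exertrack_input_error")
  }
  invisible(joint)
}

#' Build a frame stream from joint positions
#'
#' A frame stream is a tidy tibble with one row per joint per frame and
#' columns `time` (seconds), `joint`, `x`, `y`, `z` (metres, camera space),
#' carrying the nominal frame rate as an attribute. Every frame must contain
#' all 25 joints and timestamps must be strictly increasing.
#'
#' @param data A data frame with columns `time`, `joint`, `x`, `y`, `z`.
#' @param nominal_rate Nominal frame rate in frames per second (default 30,
#'   the sensor's skeletal update rate).
#' @return A `frame_stream` tibble.
#' @export
#' @examples
#' pose <- standing_pose(body_model(1.70))
#' fs <- frame_stream(pose_to_frame(pose, time = 0))
#' nominal_rate(fs)
frame_stream <- function(data, nominal_rate = 30) {
  if (!is.data.frame(data)) {
    abort("`data` must be a data frame", class = "exertrack_input_error")
  }
  need <- c("time", "joint", "x", "y", "z")
  miss <- setdiff(need, names(data))
  if (length(miss) > 0) {
    abort(paste0("frame stream is missing column(s): ",
                 paste(miss, collapse = ", ")),
          class = "exertrack_format_error")
  }
  if (!is.numeric(nominal_rate) || length(nominal_rate) != 1 ||
      nominal_rate <= 0) {
    abort("`nominal_rate` must be a single positive number",
          class = "exertrack_input_error")
  }
  out <- tibble::as_tibble(data[need])
  check_joint(unique(out$joint))
  times <- unique(out$time)
  if (is.unsorted(times, strictly = TRUE)) {
    abort("frame timestamps must be strictly increasing",
          class = "exertrack_format_error")
  }
  counts <- table(out$time)
  if (any(counts != 25)) {
    bad <- names(counts)[counts != 25][1]
    abort(sprintf("frame at t=%s does not contain exactly 25 joints", bad),
          class = "exertrack_format_error")
  }
  attr(out, "nominal_rate") <- nominal_rate
  class(out) <- c("frame_stream", class(tibble::tibble()))
  out
}

#' @rdname frame_stream
#' @param stream A `frame_stream`.
#' @export
nominal_rate <- function(stream) {
  attr(stream, "nominal_rate") %||% 30
}

#' @rdname frame_stream
#' @export
is_frame_stream <- function(stream) inherits(stream, "frame_stream")

#' Convert a named position matrix to one tidy frame
#'
#' @param pose A 25 x 3 matrix with joint row names and x, y, z columns.
#' @param time Timestamp in seconds.
#' @return A tibble with columns `time`, `joint`, `x`, `y`, `z`.
#' @export
pose_to_frame <- function(pose, time = 0) {
  stopifnot(is.matrix(pose), ncol(pose) == 3, !is.null(rownames(pose)))
  tibble::tibble(
    time = time, joint = rownames(pose),
    x = unname(pose[, 1]), y = unname(pose[, 2]), z = unname(pose[, 3])
  )
}

# Internal dense view of a stream: list(time = n-vector,
# pos = n x 25 x 3 array with joint dimnames).
stream_arrays <- function(stream) {
  joints <- kinect_joints()
  times <- unique(stream$time)
  n <- length(times)
  idx_j <- match(stream$joint, joints)
  idx_t <- match(stream$time, times)
  pos <- array(NA_real_, dim = c(n, 25, 3),
               dimnames = list(NULL, joints, c("x", "y", "z")))
  pos[cbind(idx_t, idx_j, 1)] <- stream$x
  pos[cbind(idx_t, idx_j, 2)] <- stream$y
  pos[cbind(idx_t, idx_j, 3)] <- stream$z
  list(time = times, pos = pos)
}

# n x 3 matrix trajectory of one joint
joint_traj <- function(arr, joint) {
  arr$pos[, joint, , drop = FALSE][, 1, ]
}

joint_traj_m <- function(arr, joint) {
  m <- arr$pos[, joint, , drop = FALSE]
  matrix(m, nrow = dim(m)[1], ncol = 3,
         dimnames = list(NULL, c("x", "y", "z")))
}

#' Flag frames whose joints fall outside the sensor depth range
#'
#' The sensor tracks reliably only within a depth working range of
#' 0.4 to 4.5 m; a frame with any joint depth (z) outside that interval is
#' flagged out of range. Flagged frames are kept, not dropped; assessment
#' refuses streams with too high a flagged fraction.
#'
#' @param stream A `frame_stream`.
#' @return A tibble with columns `time` and `out_of_range` (logical), one row
#'   per frame.
#' @export
flag_out_of_range <- function(stream) {
  stream |>
    dplyr::group_by(.data$time) |>
    dplyr::summarise(
      out_of_range = any(.data$z < DEPTH_RANGE_M[1] - 1e-9 |
                           .data$z > DEPTH_RANGE_M[2] + 1e-9),
      .groups = "drop"
    )
}

#' Displacement vector and length between two joints
#'
#' For each frame, the 3D displacement from joint `a` to joint `b` and its
#' Euclidean length. These segments model limb vectors, e.g. the arm
#' (shoulder to elbow) and forearm (elbow to wrist).
#'
#' @param stream A `frame_stream` (one or more frames).
#' @param a,b Joint identifiers (see [kinect_joints()]); must differ.
#' @return A tibble with columns `time`, `dx`, `dy`, `dz`, `length`.
#' @export
#' @examples
#' fs <- frame_stream(pose_to_frame(standing_pose(body_model())))
#' segment(fs, "SHOULDER_RIGHT", "ELBOW_RIGHT")
segment <- function(stream, a, b) {
  check_joint(c(a, b))
  if (identical(a, b)) {
    abort("`a` and `b` must be distinct joints",
          class = "exertrack_input_error")
  }
  arr <- stream_arrays(stream)
  pa <- joint_traj_m(arr, a)
  pb <- joint_traj_m(arr, b)
  d <- pb - pa
  tibble::tibble(
    time = arr$time,
    dx = as.numeric(d[, 1]), dy = as.numeric(d[, 2]),
    dz = as.numeric(d[, 3]),
    length = row_norms(d)
  )
}

#' Angle at a joint between two segments
#'
#' For each frame, the angle at `vertex` between the segments `vertex -> a`
#' and `vertex -> c`, in degrees within \[0, 180\]. This is the range-of-motion
#' primitive: e.g. the knee angle between the thigh (knee to hip) and the
#' lower leg (knee to ankle), 180 when standing upright and 90 when the
#' thighs are parallel to the floor.
#'
#' @param stream A `frame_stream`.
#' @param a,vertex,c Three distinct joint identifiers.
#' @return A numeric vector of angles in degrees, one per frame.
#' @export
#' @examples
#' fs <- frame_stream(pose_to_frame(standing_pose(body_model())))
#' joint_angle(fs, "HIP_RIGHT", "KNEE_RIGHT", "ANKLE_RIGHT")
joint_angle <- function(stream, a, vertex, c) {
  check_joint(c(a, vertex, c))
  if (anyDuplicated(c(a, vertex, c))) {
    abort("`a`, `vertex` and `c` must be three distinct joints",
          class = "exertrack_input_error")
  }
  arr <- stream_arrays(stream)
  u <- joint_traj_m(arr, a) - joint_traj_m(arr, vertex)
  v <- joint_traj_m(arr, c) - joint_traj_m(arr, vertex)
  if (any(row_norms(u) == 0) || any(row_norms(v) == 0)) {
    abort("degenerate pose: zero-length segment at the angle vertex",
          class = "exertrack_degenerate_pose_error")
  }
  angle_between_rows(u, v)
}

#' Torso tilt relative to the vertical
#'
#' For each frame, the angle in degrees between the SPINE_BASE to
#' SPINE_SHOULDER vector and the world vertical (+y) axis. Arm abduction or
#' flexion in older users often comes with a compensatory torso tilt; this
#' angle is checked against the tolerance profile's tilt limit.
#'
#' @param stream A `frame_stream`.
#' @return A numeric vector of tilt angles in degrees, one per frame.
#' @export
torso_tilt <- function(stream) {
  arr <- stream_arrays(stream)
  u <- joint_traj_m(arr, "SPINE_SHOULDER") - joint_traj_m(arr, "SPINE_BASE")
  if (any(row_norms(u) == 0)) {
    abort("degenerate pose: SPINE_BASE and SPINE_SHOULDER coincide",
          class = "exertrack_degenerate_pose_error")
  }
  up <- matrix(rep(c(0, 1, 0), each = nrow(u)), ncol = 3)
  angle_between_rows(u, up)
}
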