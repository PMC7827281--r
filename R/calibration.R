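#' Calibrate a biometric profile from a resting stream
#'
#' Each exercise session starts with a calibration: the user stands relaxed
#' in front of the sensor and the resting position of every joint is taken
#' as the per-joint coordinate-wise mean over the stream. Limb vectors of
#' biometric nature are derived from the means — the arm (shoulder to elbow,
#' SE) and forearm (elbow to wrist, EW) on the chosen side, and likewise the
#' thigh (HK) and shank (KA). These are user-specific and reused as the
#' reference state by the assessment functions.
#'
#' The stream must be stationary: if any joint's positional standard
#' deviation along any axis exceeds `motion_sd_limit` the calibration fails.
#' The default limit of 2 cm is deliberately generous, to accommodate the
#' postural sway of older adults.
#'
#' @param stream A `frame_stream` of at least one second at the nominal rate.
#' @param side `"left"` or `"right"`: which arm/leg defines the limb vectors.
#' @param user_id Opaque identifier stored in the profile.
#' @param motion_sd_limit Stationarity threshold: maximum per-joint, per-axis
#'   positional sd in metres (default 0.02).
#' @param max_out_of_range Maximum tolerated fraction of depth-flagged frames
#'   (default 0.1).
#' @return A `biometric_profile`: resting positions (tibble), limb vectors
#'   and lengths, `upper_limb_length` (|SE| + |EW|), `lower_limb_length`
#'   (|HK| + |KA|), `user_height` (vertical extent from HEAD to the lower
#'   FOOT joint) and resting angles of the controlled joints.
#' @export
#' @examples
#' fs <- simulate_static(body_model(), duration_s = 1.5)
#' prof <- calibrate(fs, side = "right")
#' prof$upper_limb_length
calibrate <- function(stream, side = c("right", "left"), user_id = "user",
                      motion_sd_limit = 0.02, max_out_of_range = 0.1) {
  side <- match.arg(side)
  arr <- stream_arrays(stream)
  n <- length(arr$time)
  rate <- nominal_rate(stream)
  if ((n - 1) / rate < 1 - 1e-9) {
    abort("calibration stream must span at least 1 second",
          class = "exertrack_calibration_error")
  }
  oor <- flag_out_of_range(stream)
  if (mean(oor$out_of_range) > max_out_of_range) {
    abort(sprintf(
      "capture error: %.0f%% of frames have joints outside the %.1f-%.1f m depth range",
      100 * mean(oor$out_of_range), DEPTH_RANGE_M[1], DEPTH_RANGE_M[2]),
      class = "exertrack_capture_error")
  }
  sds <- apply(arr$pos, c(2, 3), sd)
  if (any(sds > motion_sd_limit)) {
    worst <- which(sds == max(sds), arr.ind = TRUE)[1, ]
    abort(sprintf(
      "calibration failed: user not stationary (joint %s sd %.1f mm exceeds %.0f mm)",
      rownames(sds)[worst[1]], 1000 * max(sds), 1000 * motion_sd_limit),
      class = "exertrack_calibration_error")
  }
  mean_pos <- apply(arr$pos, c(2, 3), mean)
  profile_from_mean(mean_pos, side, user_id, rate)
}

# Build the profile object from a 25 x 3 matrix of resting positions.
profile_from_mean <- function(mean_pos, side, user_id, rate) {
  su <- toupper(side)
  jn <- function(stem) mean_pos[paste0(stem, "_", su), ]
  se <- jn("ELBOW") - jn("SHOULDER")
  ew <- jn("WRIST") - jn("ELBOW")
  hk <- jn("KNEE") - jn("HIP")
  ka <- jn("ANKLE") - jn("KNEE")
  lens <- vapply(list(se, ew, hk, ka), function(v) sqrt(sum(v^2)), 0)
  if (any(lens == 0)) {
    abort("degenerate pose: zero-length limb segment in the resting pose",
          class = "exertrack_degenerate_pose_error")
  }

  resting <- tibble::tibble(
    joint = rownames(mean_pos),
    x = unname(mean_pos[, 1]), y = unname(mean_pos[, 2]),
    z = unname(mean_pos[, 3])
  )
  mean_stream <- frame_stream(
    dplyr::mutate(resting, time = 0, .before = 1), nominal_rate = rate)
  resting_angles <- c(
    arm = unname(controlled_arm_angle(mean_stream, side)),
    knee_left = unname(joint_angle(mean_stream, "HIP_LEFT", "KNEE_LEFT",
                                   "ANKLE_LEFT")),
    knee_right = unname(joint_angle(mean_stream, "HIP_RIGHT", "KNEE_RIGHT",
                                    "ANKLE_RIGHT")),
    elbow = unname(joint_angle(mean_stream, paste0("SHOULDER_", su),
                               paste0("ELBOW_", su), paste0("WRIST_", su)))
  )

  structure(list(
    user_id = user_id,
    side = side,
    resting_positions = resting,
    arm_vector = se, forearm_vector = ew,
    thigh_vector = hk, shank_vector = ka,
    arm_length = lens[1], forearm_length = lens[2],
    thigh_length = lens[3], shank_length = lens[4],
    upper_limb_length = lens[1] + lens[2],
    lower_limb_length = lens[3] + lens[4],
    user_height = mean_pos["HEAD", 2] -
      min(mean_pos["FOOT_LEFT", 2], mean_pos["FOOT_RIGHT", 2]),
    resting_angles = resting_angles,
    nominal_rate = rate
  ), class = "biometric_profile")
}

#' @export
print.biometric_profile <- function(x, ...) {
  cat("<biometric_profile>", x$user_id, "side:", x$side, "\n")
  cat(sprintf("  upper limb %.3f m  lower limb %.3f m  height %.3f m\n",
              x$upper_limb_length, x$lower_limb_length, x$user_height))
  cat("  resting angles:",
      paste(sprintf("%s=%.1f", names(x$resting_angles), x$resting_angles),
            collapse = "  "), "\n")
  invisible(x)
}

resting_position <- function(profile, joint) {
  m <- profile$resting_positions
  as.numeric(m[m$joint == joint, c("x", "y", "z")])
}

#' Goal coordinate for a target angle
#'
#' Computes the 3D point the hand should reach for a concentric shoulder
#' exercise with a given target angle: the endpoint of the straight upper
#' limb (length `upper_limb_length`) anchored at the resting shoulder
#' position and rotated by the target angle from the resting downward
#' direction, within the user's frontal plane (camera x-y; the user faces
#' the sensor). The goal depends on the user's position in the scene, the
#' target angle and the upper-limb length, and is reported with a precision
#' of 5 decimal places.
#'
#' @param profile A `biometric_profile` from [calibrate()].
#' @param target_angle Target angle in degrees, in (0, 180].
#' @return A one-row tibble with columns `x`, `y`, `z` (metres, rounded to
#'   5 decimals).
#' @export
goal_position <- function(profile, target_angle) {
  stopifnot(inherits(profile, "biometric_profile"))
  if (!is.numeric(target_angle) || length(target_angle) != 1 ||
      target_angle <= 0 || target_angle > 180) {
    abort("`target_angle` must be a single angle in (0, 180] degrees",
          class = "exertrack_input_error")
  }
  sh <- resting_position(profile, paste0("SHOULDER_", toupper(profile$side)))
  sp <- resting_position(profile, "SPINE_SHOULDER")
  lat <- sign(sh[1] - sp[1])
  if (lat == 0) lat <- if (profile$side == "left") 1 else -1
  a <- deg2rad(target_angle)
  dir <- c(lat * sin(a), -cos(a), 0)
  goal <- sh + profile$upper_limb_length * dir
  tibble::tibble(x = round5(goal[1]), y = round5(goal[2]), z = round5(goal[3]))
}

#' Serialize / read a biometric profile
#'
#' Profiles are stored as a versioned key-value text document so that the
#' calibration can be captured once and retrieved at the beginning of the
#' related exercise.
#'
#' @param profile A `biometric_profile`.
#' @param path File path.
#' @return `write_profile()` returns `path` invisibly; `read_profile()`
#'   returns a `biometric_profile`.
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "biometric_profile"))
  num <- function(x) paste(sprintf("%.9f", x), collapse = ",")
  lines <- c(
    "exertrack_profile: v1",
    paste0("user_id: ", profile$user_id),
    paste0("side: ", profile$side),
    paste0("nominal_rate: ", num(profile$nominal_rate)),
    paste0("user_height: ", num(profile$user_height)),
    paste0("resting_angles: ",
           paste(names(profile$resting_angles), collapse = ",")),
    paste0("resting_angle_values: ", num(profile$resting_angles)),
    vapply(seq_len(nrow(profile$resting_positions)), function(i) {
      r <- profile$resting_positions[i, ]
      paste0("joint ", r$joint, ": ", num(c(r$x, r$y, r$z)))
    }, "")
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_profile
#' @export
read_profile <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0 || !startsWith(lines[1], "exertrack_profile:")) {
    abort("not an exertrack profile document",
          class = "exertrack_format_error")
  }
  kv <- strsplit(lines, ": ", fixed = TRUE)
  keys <- vapply(kv, `[`, "", 1)
  vals <- vapply(kv, function(p) paste(p[-1], collapse = ": "), "")
  get <- function(k) vals[match(k, keys)]
  nums <- function(s) as.numeric(strsplit(s, ",", fixed = TRUE)[[1]])
  jrows <- grepl("^joint ", keys)
  pos <- tibble::tibble(
    joint = sub("^joint ", "", keys[jrows]),
    mat = lapply(vals[jrows], nums)
  )
  resting <- tibble::tibble(
    joint = pos$joint,
    x = vapply(pos$mat, `[`, 0, 1),
    y = vapply(pos$mat, `[`, 0, 2),
    z = vapply(pos$mat, `[`, 0, 3)
  )
  rate <- nums(get("nominal_rate"))
  fs <- frame_stream(dplyr::mutate(resting, time = 0, .before = 1),
                     nominal_rate = rate)
  mean_pos <- as.matrix(resting[, c("x", "y", "z")])
  rownames(mean_pos) <- resting$joint
  mean_pos <- mean_pos[kinect_joints(), , drop = FALSE]
  profile_from_mean(mean_pos, get("side"), get("user_id"), rate)
}
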