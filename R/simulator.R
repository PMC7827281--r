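#' Parametric body model
#'
#' Segment lengths scaled from stature by fixed anthropometric ratios
#' (documented constants; left/right symmetric). These drive the synthetic
#' pose builder and the exercise trajectory generators.
#'
#' @param height Stature in metres (default 1.70).
#' @return A list of class `body_model` with the stature and derived segment
#'   lengths/levels (metres).
#' @export
#' @examples
#' body_model(1.65)$upper_arm
body_model <- function(height = 1.70) {
  if (!is.numeric(height) || length(height) != 1 || height <= 0) {
    abort("`height` must be a single positive number",
          class = "exertrack_input_error")
  }
  h <- height
  structure(list(
    height = h,
    # vertical joint levels above the floor
    head_y = 0.936 * h,
    neck_y = 0.870 * h,
    shoulder_y = 0.818 * h,
    spine_mid_y = 0.674 * h,
    hip_y = 0.530 * h,
    knee_y = 0.285 * h,
    ankle_y = 0.039 * h,
    # segment lengths
    upper_arm = 0.186 * h,
    forearm = 0.146 * h,
    hand = 0.026 * h,
    thigh = 0.245 * h,          # hip_y - knee_y
    shank = 0.246 * h,          # knee_y - ankle_y
    shoulder_half_width = 0.129 * h,
    hip_half_width = 0.064 * h,
    foot_length = 0.050 * h     # toes point toward the sensor
  ), class = "body_model")
}

#' Canonical standing pose
#'
#' Builds a 25 x 3 position matrix for an upright standing pose facing the
#' sensor, arms hanging down, at a given camera depth. The user's left side
#' is at +x (the camera mirrors the scene), anterior is -z.
#'
#' @param body A [body_model()].
#' @param distance Camera depth of the body plane in metres (default 2).
#' @return A 25 x 3 matrix with joint row names.
#' @export
standing_pose <- function(body, distance = 2) {
  stopifnot(inherits(body, "body_model"))
  z <- distance
  sw <- body$shoulder_half_width
  hw <- body$hip_half_width
  p <- matrix(NA_real_, nrow = 25, ncol = 3,
              dimnames = list(kinect_joints(), c("x", "y", "z")))
  p["SPINE_BASE", ] <- c(0, body$hip_y, z)
  p["SPINE_MID", ] <- c(0, body$spine_mid_y, z)
  p["SPINE_SHOULDER", ] <- c(0, body$shoulder_y, z)
  p["NECK", ] <- c(0, body$neck_y, z)
  p["HEAD", ] <- c(0, body$head_y, z)
  for (side in c("LEFT", "RIGHT")) {
    sgn <- if (side == "LEFT") 1 else -1
    sx <- sgn * sw
    p[paste0("SHOULDER_", side), ] <- c(sx, body$shoulder_y, z)
    ey <- body$shoulder_y - body$upper_arm
    p[paste0("ELBOW_", side), ] <- c(sx, ey, z)
    wy <- ey - body$forearm
    p[paste0("WRIST_", side), ] <- c(sx, wy, z)
    hy <- wy - body$hand
    p[paste0("HAND_", side), ] <- c(sx, hy, z)
    p[paste0("HAND_TIP_", side), ] <- c(sx, hy - 0.02 * body$height, z)
    p[paste0("THUMB_", side), ] <- c(sx - sgn * 0.03 * body$height, wy, z)
    hx <- sgn * hw
    p[paste0("HIP_", side), ] <- c(hx, body$hip_y, z)
    p[paste0("KNEE_", side), ] <- c(hx, body$knee_y, z)
    p[paste0("ANKLE_", side), ] <- c(hx, body$ankle_y, z)
    p[paste0("FOOT_", side), ] <- c(hx, 0, z - body$foot_length)
  }
  p
}

# Raised-cosine activation profile for one repetition: 0 -> 1 -> 0 over
# rep_s seconds, hitting exactly 1 at the midpoint. Returns s(t) for a
# global time vector, given rep start times.
rep_profile <- function(time, starts, rep_s) {
  s <- numeric(length(time))
  for (t0 in starts) {
    inside <- time >= t0 & time <= t0 + rep_s
    s[inside] <- pmax(s[inside], (1 - cos(2 * pi * (time[inside] - t0) / rep_s)) / 2)
  }
  s
}

# Exact sampling grid: integer frame indices over the rate, so that grid
# points at whole/half seconds are representable exactly.
time_grid <- function(total_s, rate) {
  (0:round(total_s * rate)) / rate
}

add_noise <- function(mat, sd) {
  if (sd <= 0) return(mat)
  mat + matrix(rnorm(length(mat), sd = sd), nrow = nrow(mat))
}

frames_to_stream <- function(frame_list, times, rate) {
  joints <- kinect_joints()
  n <- length(frame_list)
  df <- tibble::tibble(
    time = rep(times, each = 25),
    joint = rep(joints, times = n),
    x = unlist(lapply(frame_list, function(p) p[joints, 1]), use.names = FALSE),
    y = unlist(lapply(frame_list, function(p) p[joints, 2]), use.names = FALSE),
    z = unlist(lapply(frame_list, function(p) p[joints, 3]), use.names = FALSE)
  )
  frame_stream(df, nominal_rate = rate)
}

#' Simulate a stationary stream
#'
#' Repeats a standing pose (optionally with per-frame Gaussian jitter) for a
#' given duration; the input expected by [calibrate()].
#'
#' @param body A [body_model()].
#' @param duration_s Stream duration in seconds.
#' @param rate Frame rate, frames per second.
#' @param noise_sd_m Per-joint, per-frame Gaussian jitter sd in metres.
#' @param distance Camera depth in metres.
#' @param seed Optional integer seed (noise only).
#' @param pose Optional 25 x 3 pose matrix overriding the standing pose.
#' @return A `frame_stream`.
#' @export
simulate_static <- function(body, duration_s = 2, rate = 30, noise_sd_m = 0,
                            distance = 2, seed = NULL, pose = NULL) {
  if (!is.null(seed)) set.seed(seed)
  base <- pose %||% standing_pose(body, distance)
  times <- time_grid(duration_s, rate)
  frames <- lapply(times, function(t) add_noise(base, noise_sd_m))
  frames_to_stream(frames, times, rate)
}

#' Simulate a concentric shoulder exercise (abduction/flexion)
#'
#' Generates a synthetic stream of a lateral arm raise: the straight arm
#' rotates in the frontal plane from hanging down to a commanded peak angle
#' and back, following a raised-cosine profile, so the commanded extremum is
#' achieved exactly (before noise) at a frame on the sampling grid. An
#' optional compensatory torso tilt (the whole upper body leaning sideways,
#' arm carried along) can be injected, either for the whole stream or only
#' during the middle third of each repetition.
#'
#' @param body A [body_model()].
#' @param peak_deg Commanded peak abduction angle, degrees in (0, 180].
#' @param n_reps Number of repetitions.
#' @param rep_s Duration of one repetition in seconds; `rep_s * rate / 2`
#'   must be a whole number so the peak lands on a frame.
#' @param rest_s Rest before, between and after repetitions, seconds.
#' @param rate Frame rate, frames per second.
#' @param noise_sd_m Per-joint, per-frame Gaussian jitter sd in metres.
#' @param tilt_deg Injected torso tilt, degrees.
#' @param tilt_mode `"none"`, `"constant"` (whole stream) or `"mid_rep"`
#'   (middle third of each repetition).
#' @param side `"left"` or `"right"` arm.
#' @param distance Camera depth in metres.
#' @param seed Optional integer seed (noise only).
#' @return A `frame_stream`.
#' @export
simulate_abduction <- function(body, peak_deg = 90, n_reps = 1, rep_s = 4,
                               rest_s = 1, rate = 30, noise_sd_m = 0,
                               tilt_deg = 0,
                               tilt_mode = c("none", "constant", "mid_rep"),
                               side = c("right", "left"),
                               distance = 2, seed = NULL) {
  side <- match.arg(side)
  tilt_mode <- match.arg(tilt_mode)
  if (peak_deg <= 0 || peak_deg > 180) {
    abort("`peak_deg` must lie in (0, 180]", class = "exertrack_input_error")
  }
  if (!is.null(seed)) set.seed(seed)
  base <- standing_pose(body, distance)
  total <- rest_s + n_reps * (rep_s + rest_s)
  times <- time_grid(total, rate)
  starts <- rest_s + (seq_len(n_reps) - 1) * (rep_s + rest_s)
  s <- rep_profile(times, starts, rep_s)
  theta <- peak_deg * s

  side_u <- toupper(side)
  arm_joints <- paste0(c("ELBOW_", "WRIST_", "HAND_", "HAND_TIP_", "THUMB_"),
                       side_u)
  shoulder <- paste0("SHOULDER_", side_u)
  lat_sgn <- if (side_u == "LEFT") 1 else -1
  upper <- c("SPINE_MID", "SPINE_SHOULDER", "NECK", "HEAD",
             "SHOULDER_LEFT", "SHOULDER_RIGHT",
             paste0(c("ELBOW_", "WRIST_", "HAND_", "HAND_TIP_", "THUMB_"),
                    rep(c("LEFT", "RIGHT"), each = 5)))

  tilt_at <- switch(tilt_mode,
    none = rep(0, length(times)),
    constant = rep(tilt_deg, length(times)),
    mid_rep = {
      on <- rep(FALSE, length(times))
      for (t0 in starts) {
        on <- on | (times >= t0 + rep_s / 3 & times <= t0 + 2 * rep_s / 3)
      }
      ifelse(on, tilt_deg, 0)
    }
  )

  frames <- lapply(seq_along(times), function(i) {
    p <- base
    # raise the arm: rotate the arm chain about the shoulder, away from the
    # body in the frontal plane
    off <- sweep(p[arm_joints, , drop = FALSE], 2, p[shoulder, ])
    ang <- lat_sgn * theta[i]
    a <- deg2rad(ang)
    rot <- cbind(off[, 1] * cos(a) - off[, 2] * sin(a),
                 off[, 1] * sin(a) + off[, 2] * cos(a),
                 off[, 3])
    p[arm_joints, ] <- sweep(rot, 2, p[shoulder, ], "+")
    # compensatory lean of the whole upper body about SPINE_BASE
    if (tilt_at[i] != 0) {
      offu <- sweep(p[upper, , drop = FALSE], 2, p["SPINE_BASE", ])
      a <- deg2rad(tilt_at[i])
      rotu <- cbind(offu[, 1] * cos(a) - offu[, 2] * sin(a),
                    offu[, 1] * sin(a) + offu[, 2] * cos(a),
                    offu[, 3])
      p[upper, ] <- sweep(rotu, 2, p["SPINE_BASE", ], "+")
    }
    add_noise(p, noise_sd_m)
  })
  frames_to_stream(frames, times, rate)
}

#' Simulate a double-leg squat
#'
#' The knee angle descends from 180 (upright) to a commanded minimum and
#' back (raised cosine), by rotating the thigh backwards about the knee; the
#' pelvis and upper body follow the hips rigidly. A commanded anteroposterior
#' knee advance beyond the foot joint (knee-over-toe deviation) can be
#' injected; its maximum over the stream equals `knee_advance_cm` exactly.
#'
#' @inheritParams simulate_abduction
#' @param min_angle_deg Commanded minimum knee angle, degrees in (0, 180).
#' @param knee_advance_cm Commanded peak anteroposterior knee advance beyond
#'   the foot joint, centimetres.
#' @return A `frame_stream`.
#' @export
simulate_squat <- function(body, min_angle_deg = 100, n_reps = 1, rep_s = 4,
                           rest_s = 1, rate = 30, noise_sd_m = 0,
                           knee_advance_cm = 0, distance = 2, seed = NULL) {
  if (min_angle_deg <= 0 || min_angle_deg >= 180) {
    abort("`min_angle_deg` must lie in (0, 180)",
          class = "exertrack_input_error")
  }
  if (!is.null(seed)) set.seed(seed)
  base <- standing_pose(body, distance)
  total <- rest_s + n_reps * (rep_s + rest_s)
  times <- time_grid(total, rate)
  starts <- rest_s + (seq_len(n_reps) - 1) * (rep_s + rest_s)
  s <- rep_profile(times, starts, rep_s)

  upper <- c("SPINE_BASE", "SPINE_MID", "SPINE_SHOULDER", "NECK", "HEAD",
             paste0(c("SHOULDER_", "ELBOW_", "WRIST_", "HAND_", "HAND_TIP_",
                      "THUMB_"), rep(c("LEFT", "RIGHT"), each = 6)))
  adv_m <- knee_advance_cm / 100
  z_foot <- base["FOOT_LEFT", "z"]
  z_knee0 <- base["KNEE_LEFT", "z"]

  frames <- lapply(seq_along(times), function(i) {
    p <- base
    si <- s[i]
    phi <- 180 - (180 - min_angle_deg) * si       # knee interior angle
    z_knee <- z_knee0 + (z_foot - adv_m - z_knee0) * si
    for (side in c("LEFT", "RIGHT")) {
      knee <- paste0("KNEE_", side)
      ankle <- paste0("ANKLE_", side)
      hip <- paste0("HIP_", side)
      p[knee, "z"] <- z_knee
      # thigh direction: rotate the ankle->knee direction by (180 - phi)
      # about the knee, backwards (+z), so the interior knee angle is phi
      u <- p[knee, ] - p[ankle, ]
      u <- u / sqrt(sum(u^2))
      psi <- atan2(u["z"], u["y"]) + deg2rad(180 - phi)
      v <- c(0, cos(psi), sin(psi))
      p[hip, c("y", "z")] <- p[knee, c("y", "z")] + body$thigh * v[2:3]
    }
    # pelvis and upper body ride on the hips, staying vertical
    hip_mid <- (p["HIP_LEFT", ] + p["HIP_RIGHT", ]) / 2
    hip_mid0 <- (base["HIP_LEFT", ] + base["HIP_RIGHT", ]) / 2
    shift <- hip_mid - hip_mid0
    p[upper, ] <- sweep(base[upper, , drop = FALSE], 2, shift, "+")
    add_noise(p, noise_sd_m)
  })
  frames_to_stream(frames, times, rate)
}

#' Simulate an isometric scapular retraction
#'
#' Generates a stream in which the shoulders pull back and slightly together
#' (both moving away from the sternum) for a commanded symmetric hold, then
#' release. Outside the hold plateau the shoulders drift slowly forward and
#' inward (protraction), so the retraction conditions fail there and the
#' recovered hold duration equals the commanded plateau. An optional constant
#' asymmetry offsets the left-shoulder distance so that
#' `abs(|RS| - |LS|) == asymmetry_m` throughout.
#'
#' @inheritParams simulate_abduction
#' @param hold_s Commanded symmetric hold (plateau) duration, seconds.
#' @param pre_s,post_s Pre/post phase durations, seconds.
#' @param retract_in_m Inward x displacement of each shoulder at full
#'   retraction, metres.
#' @param retract_back_m Backward (+z) displacement of each shoulder at full
#'   retraction, metres.
#' @param asymmetry_m Constant imposed difference between the right- and
#'   left-shoulder distances to SPINE_SHOULDER, metres.
#' @return A `frame_stream`.
#' @export
simulate_retraction <- function(body, hold_s = 4, pre_s = 1, post_s = 1,
                                rate = 30, retract_in_m = 0.010,
                                retract_back_m = 0.080, asymmetry_m = 0,
                                noise_sd_m = 0, distance = 2, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  base <- standing_pose(body, distance)
  total <- pre_s + hold_s + post_s
  times <- time_grid(total, rate)
  in_hold <- times >= pre_s & times <= pre_s + hold_s
  # slow protraction drift outside the hold (keeps the monotone-deformation
  # conditions false there); drift is strictly smaller than the retraction
  # inset so the plateau always dominates earlier frames
  drift_in <- retract_in_m * 0.9

  frames <- lapply(seq_along(times), function(i) {
    p <- base
    t <- times[i]
    if (in_hold[i]) {
      dx <- retract_in_m
      dz <- retract_back_m
    } else {
      prog <- if (t < pre_s) t / pre_s else (t - pre_s - hold_s) / post_s
      dx <- drift_in * prog
      dz <- 0
    }
    p["SHOULDER_LEFT", "x"] <- p["SHOULDER_LEFT", "x"] - dx
    p["SHOULDER_RIGHT", "x"] <- p["SHOULDER_RIGHT", "x"] + dx
    p[c("SHOULDER_LEFT", "SHOULDER_RIGHT"), "z"] <-
      p[c("SHOULDER_LEFT", "SHOULDER_RIGHT"), "z"] + dz
    if (asymmetry_m != 0) {
      # rescale the left-shoulder offset so |LS| = |RS| - asymmetry_m
      s0 <- p["SPINE_SHOULDER", ]
      rs <- sqrt(sum((p["SHOULDER_RIGHT", ] - s0)^2))
      off <- p["SHOULDER_LEFT", ] - s0
      p["SHOULDER_LEFT", ] <- s0 + off * (rs - asymmetry_m) / sqrt(sum(off^2))
    }
    add_noise(p, noise_sd_m)
  })
  frames_to_stream(frames, times, rate)
}

#' Simulate a horizontal hand-swipe gesture
#'
#' One hand holds at half the user's height, lateral to the trunk, then
#' sweeps horizontally toward and (optionally) past the x-coordinate of
#' SPINE_MID. An optional downward y drift, applied progressively during the
#' sweep, makes the hand leave the valid height band before crossing.
#'
#' @inheritParams simulate_abduction
#' @param cross If `TRUE` the trajectory crosses the SPINE_MID x-coordinate;
#'   if `FALSE` it stops short.
#' @param y_drift_m Total downward drift in metres, applied linearly over the
#'   sweep.
#' @param hold_s Stationary arming phase before the sweep, seconds.
#' @param sweep_s Sweep duration, seconds.
#' @return A `frame_stream`.
#' @export
simulate_swipe <- function(body, side = c("right", "left"), cross = TRUE,
                           y_drift_m = 0, hold_s = 0.5, sweep_s = 2,
                           rate = 30, noise_sd_m = 0, distance = 2,
                           seed = NULL) {
  side <- match.arg(side)
  if (!is.null(seed)) set.seed(seed)
  base <- standing_pose(body, distance)
  h_ext <- base["HEAD", "y"] - min(base["FOOT_LEFT", "y"],
                                   base["FOOT_RIGHT", "y"])
  total <- hold_s + sweep_s + 0.5
  times <- time_grid(total, rate)
  side_u <- toupper(side)
  lat_sgn <- if (side_u == "LEFT") 1 else -1
  x_spine <- base["SPINE_MID", "x"]
  x_start <- x_spine + lat_sgn * 0.28 * body$height
  x_end <- if (cross) x_spine - lat_sgn * 0.10 * body$height
           else x_spine + lat_sgn * 0.02 * body$height
  y_hand0 <- min(base["FOOT_LEFT", "y"], base["FOOT_RIGHT", "y"]) +
    0.5 * h_ext
  hand_joints <- paste0(c("HAND_", "HAND_TIP_", "THUMB_", "WRIST_"), side_u)

  frames <- lapply(seq_along(times), function(i) {
    p <- base
    t <- times[i]
    prog <- if (t <= hold_s) 0 else min(1, (t - hold_s) / sweep_s)
    hx <- x_start + (x_end - x_start) * prog
    hy <- y_hand0 - y_drift_m * prog
    hand0 <- p[paste0("HAND_", side_u), ]
    target <- c(hx, hy, hand0["z"])
    shift <- target - hand0
    p[hand_joints, ] <- sweep(p[hand_joints, , drop = FALSE], 2, shift, "+")
    p[paste0("ELBOW_", side_u), ] <-
      (p[paste0("SHOULDER_", side_u), ] + p[paste0("WRIST_", side_u), ]) / 2
    add_noise(p, noise_sd_m)
  })
  frames_to_stream(frames, times, rate)
}

#' Simulate an exercise stream from a template name
#'
#' Thin dispatcher over the specific generators, keyed by the exercise
#' template of a catalog entry.
#'
#' @param body A [body_model()].
#' @param template One of `"concentric_angle"`, `"posture_constrained_squat"`,
#'   `"isometric_hold"`.
#' @param params A named list of parameters passed to the matching generator
#'   ([simulate_abduction()], [simulate_squat()], [simulate_retraction()]).
#' @param seed Optional integer seed.
#' @return A `frame_stream`.
#' @export
simulate_exercise <- function(body, template, params = list(), seed = NULL) {
  fn <- switch(template,
    concentric_angle = simulate_abduction,
    posture_constrained_squat = simulate_squat,
    isometric_hold = simulate_retraction,
    abort(sprintf("unknown exercise template '%s'", template),
          class = "exertrack_input_error")
  )
  do.call(fn, c(list(body = body), params, list(seed = seed)))
}
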