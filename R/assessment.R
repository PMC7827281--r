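# Numeric guard for tolerance comparisons: a margin stated as "20 degrees"
# must accept a pose constructed at exactly 20 degrees despite floating-point
# rotation error.
TOL_EPS <- 1e-9

resolve_tolerance <- function(tolerance) {
  if (is.character(tolerance)) {
    return(tolerance_profile(tolerance))
  }
  if (is.data.frame(tolerance) && nrow(tolerance) == 1) {
    return(tolerance)
  }
  abort("`tolerance` must be a profile name or a one-row tolerance tibble",
        class = "exertrack_input_error")
}

spec_side <- function(spec) {
  cj <- spec$controlled_joints[[1]]
  if (any(grepl("_RIGHT$", cj)) && !any(grepl("_LEFT$", cj))) "right"
  else if (any(grepl("_LEFT$", cj)) && !any(grepl("_RIGHT$", cj))) "left"
  else "both"
}

# Smooth a per-frame angle series before extremum picking. The
# Savitzky-Golay filter (order 2) reproduces locally-quadratic peaks almost
# exactly, so noise-free extrema are preserved to well under 0.01 degrees
# while tracking jitter is attenuated.
smooth_angle <- function(x, window = 9) {
  if (length(x) < window) return(x)
  signal::sgolayfilt(x, p = 2, n = window)
}

# Hysteresis segmentation of an excursion signal (degrees away from the
# resting angle): a repetition opens when the excursion exceeds `open`,
# closes when it falls back below `close`. A repetition still open at the
# end of the stream is closed there, so truncating a stream never hides
# violations already committed.
segment_reps <- function(excursion, open = 10, close = 5) {
  n <- length(excursion)
  reps <- list()
  state <- "rest"
  start <- NA_integer_
  for (i in seq_len(n)) {
    if (state == "rest" && excursion[i] > open) {
      state <- "active"
      start <- i
    } else if (state == "active" && excursion[i] < close) {
      reps[[length(reps) + 1]] <- c(start, i)
      state <- "rest"
    }
  }
  if (state == "active") {
    reps[[length(reps) + 1]] <- c(start, n)
  }
  reps
}

# Fraction of depth-flagged frames must stay below the capture tolerance.
check_capture <- function(stream, max_out_of_range = 0.1) {
  frac <- mean(flag_out_of_range(stream)$out_of_range)
  if (frac > max_out_of_range) {
    abort(sprintf("capture error: %.0f%% of frames are outside the depth range",
                  100 * frac),
          class = "exertrack_capture_error")
  }
  invisible(frac)
}

# Controlled angle of a concentric arm exercise: the arm (shoulder ->
# wrist) against the torso-down direction (SPINE_SHOULDER -> SPINE_BASE),
# i.e. "the angle of the arm with respect to the body". Measuring against
# the torso rather than the world vertical keeps the measurement honest
# under compensatory tilt.
controlled_arm_angle <- function(stream, side) {
  su <- toupper(side)
  arr <- stream_arrays(stream)
  u <- joint_traj_m(arr, paste0("WRIST_", su)) -
    joint_traj_m(arr, paste0("SHOULDER_", su))
  v <- joint_traj_m(arr, "SPINE_BASE") - joint_traj_m(arr, "SPINE_SHOULDER")
  angle_between_rows(u, v)
}

# Controlled angle of a concentric leg exercise: knee angle.
controlled_knee_angle <- function(stream, side) {
  su <- toupper(side)
  joint_angle(stream, paste0("HIP_", su), paste0("KNEE_", su),
              paste0("ANKLE_", su))
}

rep_result_row <- function(index, measured, goal_ok, violations) {
  valid <- nrow(violations) == 0
  tibble::tibble(
    repetition = index,
    measured_angle = round5(measured),
    # an invalid repetition never counts as meeting the goal
    goal_met = goal_ok && valid,
    valid = valid,
    violations = list(violations)
  )
}

no_violations <- function() {
  tibble::tibble(rule = character(), time = numeric(), side = character())
}

#' Assess a concentric shoulder exercise
#'
#' Segments the stream into repetitions by hysteresis on the controlled
#' angle (the arm relative to the torso, relative to its calibrated resting
#' value: a repetition opens at 10 degrees of excursion and closes at 5),
#' measures the maximum range-of-motion angle of each repetition to 5
#' decimals, and applies the posture rule: the torso tilt must stay within
#' the profile's limit at every frame of the repetition. The goal is met
#' when the measured angle reaches the target minus the angular goal
#' tolerance — the margin is applied one-sided, in the direction of
#' difficulty — and the repetition is valid.
#'
#' @param stream A `frame_stream`.
#' @param profile A `biometric_profile` from [calibrate()].
#' @param spec A one-row catalog entry with `template == "concentric_angle"`.
#' @param max_out_of_range Maximum tolerated fraction of depth-flagged
#'   frames.
#' @return A tibble with one row per repetition: `repetition`,
#'   `measured_angle`, `goal_met`, `valid` and a `violations` list-column
#'   (rule, time of the first offending frame, side).
#' @export
assess_concentric <- function(stream, profile, spec,
                              max_out_of_range = 0.1) {
  stopifnot(inherits(profile, "biometric_profile"))
  if (!identical(spec$template, "concentric_angle")) {
    abort("`spec` must use the concentric_angle template",
          class = "exertrack_input_error")
  }
  check_capture(stream, max_out_of_range)
  tol <- resolve_tolerance(spec$tolerance)
  side <- spec_side(spec)
  if (side == "both") {
    abort("concentric specs must control one side",
          class = "exertrack_input_error")
  }
  leg <- any(grepl("KNEE", spec$controlled_joints[[1]]))
  raw <- if (leg) controlled_knee_angle(stream, side)
         else controlled_arm_angle(stream, side)
  sm <- smooth_angle(raw)
  resting <- if (leg) {
    profile$resting_angles[[paste0("knee_", side)]]
  } else {
    profile$resting_angles[["arm"]]
  }
  excursion <- abs(sm - resting)
  reps <- segment_reps(excursion)
  arr <- stream_arrays(stream)
  tilt <- torso_tilt(stream)

  if (length(reps) == 0) {
    warn("no repetition detected in the stream")
    return(rep_result_row(integer(), numeric(), logical(),
                          no_violations())[0, ])
  }
  purrr::map_dfr(seq_along(reps), function(r) {
    i0 <- reps[[r]][1]; i1 <- reps[[r]][2]
    win <- i0:i1
    peak_i <- win[which.max(excursion[win])]
    measured <- sm[peak_i]
    bad <- win[tilt[win] > tol$torso_tilt_limit + TOL_EPS]
    viol <- if (length(bad) > 0) {
      tibble::tibble(rule = "torso_tilt", time = arr$time[bad[1]],
                     side = NA_character_)
    } else {
      no_violations()
    }
    goal_ok <- if (leg) {
      measured <= spec$target + tol$angular_goal_tolerance + TOL_EPS
    } else {
      measured >= spec$target - tol$angular_goal_tolerance - TOL_EPS
    }
    rep_result_row(r, measured, goal_ok, viol)
  })
}

#' Assess a double-leg squat
#'
#' The correct range of motion runs from 180 degrees (upright) down to 90
#' (thighs parallel to the floor), so unlike the shoulder exercise the lower
#' the angle, the better. Repetitions are segmented on the knee-angle
#' excursion; each repetition's measure is the minimum knee angle, taken per
#' knee and reported as the worse (larger) of the two minima, to 5 decimals.
#' The posture rule is the knee-over-toe check: at every frame, neither
#' knee's anteroposterior advance beyond its FOOT joint may exceed the
#' profile's deviation limit (10 cm for the elderly profile, 0 for strict).
#'
#' @inheritParams assess_concentric
#' @param spec A one-row catalog entry with
#'   `template == "posture_constrained_squat"`.
#' @return A tibble as in [assess_concentric()]; knee-over-toe violations
#'   name the offending side.
#' @export
assess_squat <- function(stream, profile, spec, max_out_of_range = 0.1) {
  stopifnot(inherits(profile, "biometric_profile"))
  if (!identical(spec$template, "posture_constrained_squat")) {
    abort("`spec` must use the posture_constrained_squat template",
          class = "exertrack_input_error")
  }
  check_capture(stream, max_out_of_range)
  tol <- resolve_tolerance(spec$tolerance)
  arr <- stream_arrays(stream)
  raw_l <- controlled_knee_angle(stream, "left")
  raw_r <- controlled_knee_angle(stream, "right")
  sm_l <- smooth_angle(raw_l)
  sm_r <- smooth_angle(raw_r)
  exc <- pmax(abs(sm_l - profile$resting_angles[["knee_left"]]),
              abs(sm_r - profile$resting_angles[["knee_right"]]))
  reps <- segment_reps(exc)
  # anteroposterior advance of the knee beyond the foot joint, in cm;
  # the user faces the sensor, so anterior is -z and the advance is
  # z_foot - z_knee
  adv <- function(side) {
    su <- toupper(side)
    100 * pmax(0, arr$pos[, paste0("FOOT_", su), "z"] -
                 arr$pos[, paste0("KNEE_", su), "z"])
  }
  adv_l <- adv("left"); adv_r <- adv("right")

  if (length(reps) == 0) {
    warn("no repetition detected in the stream")
    return(rep_result_row(integer(), numeric(), logical(),
                          no_violations())[0, ])
  }
  purrr::map_dfr(seq_along(reps), function(r) {
    win <- reps[[r]][1]:reps[[r]][2]
    # worse (larger) of the two knees' minima
    measured <- max(min(sm_l[win]), min(sm_r[win]))
    viol <- no_violations()
    for (side in c("left", "right")) {
      a <- if (side == "left") adv_l else adv_r
      bad <- win[a[win] > tol$knee_deviation_limit + 1e-6]
      if (length(bad) > 0) {
        viol <- dplyr::bind_rows(viol, tibble::tibble(
          rule = "knee_over_toe", time = arr$time[bad[1]], side = side))
      }
    }
    goal_ok <- measured <= spec$target + tol$angular_goal_tolerance + TOL_EPS
    rep_result_row(r, measured, goal_ok, viol)
  })
}

retraction_conditions <- c(
  right_shoulder_retracting = "right",
  left_shoulder_retracting = "left",
  shoulders_approaching = "both",
  symmetric_execution = "both"
)

#' Assess an isometric scapular retraction
#'
#' Scapular retraction pulls the shoulder blades back toward the spine. With
#' R = SHOULDER_RIGHT, S = SPINE_SHOULDER and L = SHOULDER_LEFT, four
#' heuristic conditions validate the expected deformation at every frame `t`
#' at least `k` frames into the stream, against the frame `k` frames
#' earlier:
#'
#' 1. `|RS(t)| >= |RS(t-k)|` — the right shoulder keeps moving away from the
#'    sternum;
#' 2. `|LS(t)| >= |LS(t-k)|` — so does the left;
#' 3. `|RL(t)| <= |RL(t-k)|` — the shoulders approach each other;
#' 4. `abs(|RS(t)| - |LS(t)|) < epsilon` — the execution stays symmetric.
#'
#' The hold duration is the longest contiguous span over which all four
#' conditions hold simultaneously; the goal is met when it reaches
#' `hold_target` (in the gamified environment the cannon's firepower is
#' proportional to this hold, and the bullet hits the tower when the hold
#' suffices). When a condition fails, the trace identifies which one and
#' which shoulder, so the user can be told what to correct.
#'
#' @param stream A `frame_stream` longer than `k` frames.
#' @param tolerance A tolerance profile (name or one-row tibble) supplying
#'   `retraction_k` (frames) and `retraction_epsilon` (metres).
#' @param hold_target Required hold duration in seconds.
#' @return An `isometric_result`: `hold_duration` (seconds), `goal_met`, the
#'   per-frame `conditions_trace` tibble and the first failing condition per
#'   frame.
#' @export
assess_isometric_retraction <- function(stream, tolerance = "elderly",
                                        hold_target = 4) {
  tol <- resolve_tolerance(tolerance)
  k <- tol$retraction_k
  eps <- tol$retraction_epsilon
  arr <- stream_arrays(stream)
  n <- length(arr$time)
  if (n < k + 1) {
    abort(sprintf("stream has %d frames; at least k + 1 = %d are required",
                  n, k + 1),
          class = "exertrack_input_error")
  }
  s0 <- joint_traj_m(arr, "SPINE_SHOULDER")
  rs <- row_norms(joint_traj_m(arr, "SHOULDER_RIGHT") - s0)
  ls <- row_norms(joint_traj_m(arr, "SHOULDER_LEFT") - s0)
  rl <- row_norms(joint_traj_m(arr, "SHOULDER_RIGHT") -
                    joint_traj_m(arr, "SHOULDER_LEFT"))
  idx <- (k + 1):n
  lag <- idx - k
  c1 <- rs[idx] >= rs[lag] - TOL_EPS
  c2 <- ls[idx] >= ls[lag] - TOL_EPS
  c3 <- rl[idx] <= rl[lag] + TOL_EPS
  c4 <- abs(rs[idx] - ls[idx]) < eps
  all_ok <- c1 & c2 & c3 & c4
  fails <- cbind(!c1, !c2, !c3, !c4)
  first_fail <- apply(fails, 1, function(f) {
    if (any(f)) names(retraction_conditions)[which(f)[1]] else NA_character_
  })
  trace <- tibble::tibble(
    time = arr$time[idx],
    right_shoulder_retracting = c1,
    left_shoulder_retracting = c2,
    shoulders_approaching = c3,
    symmetric_execution = c4,
    all_conditions = all_ok,
    failed_condition = first_fail,
    failed_side = ifelse(is.na(first_fail), NA_character_,
                         unname(retraction_conditions[first_fail]))
  )
  # longest contiguous all-true run, measured by its timestamp span
  hold <- 0
  run_start <- NA_integer_
  best <- c(NA_integer_, NA_integer_)
  for (i in seq_along(all_ok)) {
    if (all_ok[i] && is.na(run_start)) run_start <- i
    if ((!all_ok[i] || i == length(all_ok)) && !is.na(run_start)) {
      run_end <- if (all_ok[i]) i else i - 1
      span <- trace$time[run_end] - trace$time[run_start]
      if (span > hold) {
        hold <- span
        best <- c(run_start, run_end)
      }
      run_start <- NA_integer_
    }
  }
  structure(list(
    hold_duration = hold,
    hold_target = hold_target,
    goal_met = hold >= hold_target - TOL_EPS,
    conditions_trace = trace,
    k = k, epsilon = eps,
    stream_duration = arr$time[n] - arr$time[1]
  ), class = "isometric_result")
}

#' @export
print.isometric_result <- function(x, ...) {
  cat(sprintf("<isometric_result> hold %.3f s / target %.3f s -> %s\n",
              x$hold_duration, x$hold_target,
              if (x$goal_met) "goal met" else "goal not met"))
  invisible(x)
}

#' Aggregate repetition results into a session score
#'
#' The average angle over all repetitions of an exercise performed in one
#' session is the session's performance measure (recorded to 5 decimals).
#' The score rewards achievement: 100 times the mean per-repetition
#' achievement ratio, clipped to \[0, 1\] — `measured/target` for concentric
#' exercises, `(180 - measured)/(180 - target)` for squats (lower is
#' better), and `hold/hold_target` for isometric holds.
#'
#' @param results A repetition tibble from [assess_concentric()] /
#'   [assess_squat()], or an `isometric_result`.
#' @param spec The catalog entry the results belong to.
#' @return A one-row tibble: `average_angle`, `score`, `n_repetitions`,
#'   `n_valid`, `n_goal_met`.
#' @export
score_session <- function(results, spec) {
  clip01 <- function(x) pmin(1, pmax(0, x))
  if (inherits(results, "isometric_result")) {
    ratio <- clip01(results$hold_duration / results$hold_target)
    return(tibble::tibble(
      average_angle = NA_real_, score = 100 * ratio,
      n_repetitions = 1L, n_valid = NA_integer_,
      n_goal_met = as.integer(results$goal_met)
    ))
  }
  if (!is.data.frame(results) || nrow(results) == 0) {
    abort("cannot aggregate an empty result set",
          class = "exertrack_aggregation_error")
  }
  ratio <- if (identical(spec$template, "posture_constrained_squat")) {
    (180 - results$measured_angle) / (180 - spec$target)
  } else {
    results$measured_angle / spec$target
  }
  tibble::tibble(
    average_angle = round5(mean(results$measured_angle)),
    score = 100 * mean(clip01(ratio)),
    n_repetitions = nrow(results),
    n_valid = sum(results$valid),
    n_goal_met = sum(results$goal_met)
  )
}
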