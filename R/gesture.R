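#' Recognize a horizontal hand-swipe gesture
#'
#' Rule-based finite-state recognizer for the hand swipe that advances the
#' interaction flow. A hand is in a valid starting position when its height
#' lies within a band around half the user's height (measured from the lower
#' FOOT joint) and it is laterally clear of the trunk — strictly beyond its
#' own shoulder's x-offset from SPINE_MID by a small margin. From that ARMED
#' state the hand is tracked while it moves along x keeping its height
#' approximately constant (the same band); the gesture COMPLETES at the
#' first frame where the hand's x crosses the x-coordinate of SPINE_MID
#' toward the contralateral side. Leaving the height band before crossing
#' ABORTS the episode and the recognizer returns to IDLE (it may re-arm).
#'
#' States mirror the on-screen circle colours: IDLE (grey, searching), ARMED
#' (green, starting position validated), TRACKING (green, still valid),
#' COMPLETED (light grey). COMPLETED is terminal for an episode.
#'
#' Palm orientation cannot be inferred from joint positions alone and is not
#' checked (documented limitation).
#'
#' @param stream A nonempty `frame_stream`.
#' @param user_height User height in metres (e.g. from a
#'   [calibrate()] profile's `user_height`).
#' @param band_frac Half-width of the height band as a fraction of
#'   `user_height` (default 0.1).
#' @param clearance_frac Extra lateral clearance beyond the shoulder, as a
#'   fraction of `user_height` (default 0.05).
#' @return A `swipe_result`: `completed`, `completion_time` (seconds or
#'   `NA`), `active_hand`, and a per-frame `trace` tibble of states.
#' @export
#' @examples
#' body <- body_model()
#' fs <- simulate_swipe(body, side = "right", cross = TRUE)
#' recognize_swipe(fs, user_height = 0.936 * body$height)$completed
recognize_swipe <- function(stream, user_height, band_frac = 0.1,
                            clearance_frac = 0.05) {
  if (!is.numeric(user_height) || length(user_height) != 1 ||
      user_height <= 0) {
    abort("`user_height` must be a single positive number",
          class = "exertrack_input_error")
  }
  arr <- stream_arrays(stream)
  n <- length(arr$time)
  if (n == 0) {
    abort("empty stream", class = "exertrack_input_error")
  }
  floor_y <- pmin(arr$pos[, "FOOT_LEFT", "y"], arr$pos[, "FOOT_RIGHT", "y"])
  x_spine <- arr$pos[, "SPINE_MID", "x"]
  band_lo <- 0.5 * user_height - band_frac * user_height
  band_hi <- 0.5 * user_height + band_frac * user_height

  hand_info <- function(hand) {
    su <- toupper(hand)
    hx <- arr$pos[, paste0("HAND_", su), "x"]
    hy <- arr$pos[, paste0("HAND_", su), "y"] - floor_y
    shx <- arr$pos[, paste0("SHOULDER_", su), "x"]
    list(
      in_band = hy >= band_lo & hy <= band_hi,
      clear = abs(hx - x_spine) >
        abs(shx - x_spine) + clearance_frac * user_height,
      rel_x = hx - x_spine
    )
  }
  hands <- list(right = hand_info("right"), left = hand_info("left"))

  state <- "IDLE"
  active <- "none"
  arm_sign <- 0
  states <- character(n)
  hands_trace <- character(n)
  completed <- FALSE
  completion_time <- NA_real_

  for (i in seq_len(n)) {
    if (state %in% c("ARMED", "TRACKING")) {
      h <- hands[[active]]
      if (!h$in_band[i]) {
        state <- "ABORTED"
      } else if (arm_sign * h$rel_x[i] < 0) {
        state <- "COMPLETED"
        completed <- TRUE
        completion_time <- arr$time[i]
      } else {
        state <- "TRACKING"
      }
    } else {
      if (state == "ABORTED") {
        state <- "IDLE"
        active <- "none"
        arm_sign <- 0
      }
      if (state == "IDLE") {
        for (hand in c("right", "left")) {
          h <- hands[[hand]]
          if (h$in_band[i] && h$clear[i]) {
            state <- "ARMED"
            active <- hand
            arm_sign <- sign(h$rel_x[i])
            break
          }
        }
      }
    }
    states[i] <- state
    hands_trace[i] <- active
    if (state == "COMPLETED") {
      if (i < n) {
        states[(i + 1):n] <- "COMPLETED"
        hands_trace[(i + 1):n] <- active
      }
      break
    }
  }

  structure(list(
    completed = completed,
    completion_time = completion_time,
    active_hand = if (completed) active else "none",
    trace = tibble::tibble(time = arr$time, state = states,
                           active_hand = hands_trace)
  ), class = "swipe_result")
}

#' @export
print.swipe_result <- function(x, ...) {
  if (x$completed) {
    cat(sprintf("<swipe_result> completed at %.3f s (%s hand)\n",
                x$completion_time, x$active_hand))
  } else {
    cat("<swipe_result> not completed\n")
  }
  invisible(x)
}
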