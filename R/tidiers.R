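#' Tidy a rank test result
#'
#' @param x A `rank_test` from [mann_whitney_u()], [wilcoxon_signed_rank()]
#'   or [spearman_rho()].
#' @param ... Unused.
#' @return A one-row tibble with `test`, `statistic`, `p_value`, `method`.
#' @export
tidy.rank_test <- function(x, ...) {
  tibble::tibble(
    test = x$test,
    statistic = x$statistic,
    p_value = x$p_value,
    method = x$method,
    exact = x$exact
  )
}

#' Tidy an isometric assessment
#'
#' @param x An `isometric_result` from [assess_isometric_retraction()].
#' @param ... Unused.
#' @return The per-frame conditions trace as a tibble.
#' @export
tidy.isometric_result <- function(x, ...) {
  x$conditions_trace
}

#' @rdname tidy.isometric_result
#' @export
glance.isometric_result <- function(x, ...) {
  tibble::tibble(
    hold_duration = x$hold_duration,
    hold_target = x$hold_target,
    goal_met = x$goal_met,
    k = x$k, epsilon = x$epsilon,
    stream_duration = x$stream_duration
  )
}

#' Tidy a swipe recognition result
#'
#' @param x A `swipe_result` from [recognize_swipe()].
#' @param ... Unused.
#' @return `tidy()` returns the per-frame state trace; `glance()` a one-row
#'   outcome summary.
#' @export
tidy.swipe_result <- function(x, ...) {
  x$trace
}

#' @rdname tidy.swipe_result
#' @export
glance.swipe_result <- function(x, ...) {
  tibble::tibble(
    completed = x$completed,
    completion_time = x$completion_time,
    active_hand = x$active_hand,
    n_frames = nrow(x$trace)
  )
}

#' Tidy a progress report
#'
#' @param x A `progress_report` from [progress_report()].
#' @param ... Unused.
#' @return `tidy()` returns the within-group contrast table (one row per
#'   group x exercise x session pair, with both tests' statistics and
#'   p-values); `glance()` a one-row summary of the report.
#' @export
tidy.progress_report <- function(x, ...) {
  x$within_group
}

#' @rdname tidy.progress_report
#' @export
glance.progress_report <- function(x, ...) {
  tibble::tibble(
    group_by = x$group_by,
    n_groups = length(unique(x$summaries$group)),
    n_exercises = length(unique(x$summaries$exercise_id)),
    n_sessions = length(unique(x$summaries$session)),
    n_contrasts = nrow(x$within_group),
    max_within_p = suppressWarnings(
      max(c(x$within_group$mw_p, x$within_group$wilcoxon_p), na.rm = TRUE)),
    max_between_p = if (nrow(x$between_group) > 0) {
      max(x$between_group$mw_p, na.rm = TRUE)
    } else {
      NA_real_
    }
  )
}
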