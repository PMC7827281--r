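#' Configuration of a synthetic longitudinal study
#'
#' Describes a multi-session exercise study of older adults for
#' [simulate_study()]: three age ranges (65-69, 70-74, 75-80), six sessions,
#' and two benchmark exercises (shoulder abduction, where a larger average
#' angle is better, and double-leg squat, where a smaller one is better).
#' The defaults realize the qualitative longitudinal pattern of such
#' programs: continuous session-over-session progress in every age range,
#' absolute achievement decreasing with age, and per-session improvement
#' increasing with age.
#'
#' @param participants Participants per age group (defaults 23, 19, 15 —
#'   57 in total, decreasing with age).
#' @param age_groups List of `c(lo, hi)` age ranges.
#' @param sessions Number of sessions (>= 2).
#' @param abduction_baseline,squat_baseline First-session group mean angles
#'   (degrees), one per age group.
#' @param abduction_improvement,squat_improvement Per-session change in the
#'   group mean (degrees; abduction increases, squat decreases), one per age
#'   group.
#' @param subject_sd Between-participant sd of the subject effect (degrees).
#' @param noise_sd Residual sd of a session average (degrees).
#' @return A list of class `study_config`.
#' @export
study_config <- function(participants = c(23, 19, 15),
                         age_groups = list(c(65, 69), c(70, 74), c(75, 80)),
                         sessions = 6,
                         abduction_baseline = c(100, 85, 70),
                         abduction_improvement = c(2, 3, 4),
                         squat_baseline = c(125, 140, 155),
                         squat_improvement = c(2, 3, 4),
                         subject_sd = 3, noise_sd = 1.5) {
  if (sessions < 2) {
    abort("`sessions` must be at least 2", class = "exertrack_input_error")
  }
  g <- length(age_groups)
  stopifnot(length(participants) == g,
            length(abduction_baseline) == g,
            length(abduction_improvement) == g,
            length(squat_baseline) == g,
            length(squat_improvement) == g)
  structure(list(
    participants = participants, age_groups = age_groups,
    sessions = sessions,
    abduction_baseline = abduction_baseline,
    abduction_improvement = abduction_improvement,
    squat_baseline = squat_baseline,
    squat_improvement = squat_improvement,
    subject_sd = subject_sd, noise_sd = noise_sd
  ), class = "study_config")
}

#' Simulate a longitudinal study table
#'
#' Generates one session record per participant x exercise x session:
#' `average_angle = group baseline + subject effect + (session - 1) x
#' improvement + noise`, with the squat improvement applied as an angle
#' decrease (lower is better). Deterministic given the seed. The output has
#' the same shape as a deposited physical-performance table: the average
#' angle computed for each participant, exercise and session.
#'
#' @param config A [study_config()].
#' @param seed Integer seed.
#' @return A tibble with columns `participant_id`, `age`, `gender`,
#'   `exercise_id`, `session`, `average_angle` (degrees, 5 decimals).
#' @export
#' @examples
#' head(simulate_study(study_config(), seed = 1))
simulate_study <- function(config = study_config(), seed = 1) {
  stopifnot(inherits(config, "study_config"))
  set.seed(seed)
  g <- length(config$age_groups)
  exercises <- tibble::tibble(
    exercise_id = c("shoulder_abduction", "double_leg_squat"),
    baseline = list(config$abduction_baseline, config$squat_baseline),
    step = list(config$abduction_improvement, -config$squat_improvement)
  )
  pid <- 0
  rows <- purrr::map_dfr(seq_len(g), function(gi) {
    np <- config$participants[gi]
    ages <- config$age_groups[[gi]][1] +
      (seq_len(np) - 1) %% (diff(config$age_groups[[gi]]) + 1)
    # alternate the leading gender across groups: 23+19+15 -> 29 M, 28 F
    genders <- rep(if (gi %% 2 == 1) c("M", "F") else c("F", "M"),
                   length.out = np)
    purrr::map_dfr(seq_len(np), function(pi) {
      pid <<- pid + 1
      subj <- rnorm(2, sd = config$subject_sd)   # one effect per exercise
      purrr::map_dfr(seq_len(nrow(exercises)), function(ei) {
        base <- exercises$baseline[[ei]][gi]
        step <- exercises$step[[ei]][gi]
        sess <- seq_len(config$sessions)
        mu <- base + subj[ei] + step * (sess - 1)
        tibble::tibble(
          participant_id = sprintf("P%03d", pid),
          age = ages[pi],
          gender = genders[pi],
          exercise_id = exercises$exercise_id[ei],
          session = sess,
          average_angle = round5(pmin(180, pmax(
            0, mu + rnorm(length(sess), sd = config$noise_sd))))
        )
      })
    })
  })
  rows
}

#' Label ages with the study's age ranges
#'
#' @param age Numeric ages in years.
#' @param age_groups List of `c(lo, hi)` ranges (defaults to the study's
#'   three ranges).
#' @return A factor such as `"65-69"`, with `NA` outside all ranges.
#' @export
age_group <- function(age, age_groups = list(c(65, 69), c(70, 74),
                                             c(75, 80))) {
  labels <- vapply(age_groups, function(g) sprintf("%d-%d", g[1], g[2]), "")
  out <- rep(NA_character_, length(age))
  for (i in seq_along(age_groups)) {
    g <- age_groups[[i]]
    out[age >= g[1] & age <= g[2]] <- labels[i]
  }
  factor(out, levels = labels)
}
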