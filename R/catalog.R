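#' Tolerance profiles for posture checking
#'
#' A tolerance profile bundles the margins used by the validity rules. Two
#' named profiles ship with the package:
#'
#' * `"strict"` — the margins used for young adults without injury: torso
#'   tilt up to 5 degrees, no knee advance beyond the tip of the feet.
#' * `"elderly"` — the relaxed margins for older users: the torso-tilt
#'   tolerance extended from 5 to 20 degrees and a knee-over-toe deviation of
#'   up to 10 cm allowed, so exercises remain achievable despite
#'   compensatory postures.
#'
#' The angular goal tolerance and the scapular-retraction parameters `k`
#' (frame shift for the deformation comparisons) and `epsilon` (symmetry
#' margin, metres) complete the profile; small `k`/`epsilon` values make the
#' rules demanding, larger values more permissive.
#'
#' @param name `"elderly"` or `"strict"`.
#' @param ... Named overrides for individual margins (e.g. `retraction_k`).
#' @return A one-row tibble with columns `name`, `torso_tilt_limit`
#'   (degrees), `knee_deviation_limit` (cm), `angular_goal_tolerance`
#'   (degrees), `retraction_k` (frames), `retraction_epsilon` (metres).
#' @export
#' @examples
#' tolerance_profile("elderly")
tolerance_profile <- function(name = c("elderly", "strict"), ...) {
  name <- match.arg(name)
  base <- switch(name,
    elderly = list(torso_tilt_limit = 20, knee_deviation_limit = 10,
                   angular_goal_tolerance = 5,
                   retraction_k = 10, retraction_epsilon = 0.03),
    strict = list(torso_tilt_limit = 5, knee_deviation_limit = 0,
                  angular_goal_tolerance = 2,
                  retraction_k = 10, retraction_epsilon = 0.03)
  )
  over <- list(...)
  bad <- setdiff(names(over), names(base))
  if (length(bad) > 0) {
    abort(paste0("unknown tolerance field(s): ", paste(bad, collapse = ", ")),
          class = "exertrack_input_error")
  }
  base[names(over)] <- over
  tibble::tibble(name = name, !!!base)
}

exercise_templates <- c("concentric_angle", "isometric_hold",
                        "posture_constrained_squat")

controlled_joints_for <- function(movement, side) {
  su <- toupper(side)
  switch(movement,
    abduction = ,
    flexion = ,
    rotation = ,
    extension = ,
    protraction = switch(substr(su, 1, 1),
      L = , R = {
        stems <- if (movement %in% c("extension", "protraction")) {
          c("HIP_", "KNEE_", "ANKLE_")
        } else {
          c("SHOULDER_", "ELBOW_", "WRIST_")
        }
        paste0(stems, su)
      }
    ),
    scapular_retraction = c("SHOULDER_RIGHT", "SPINE_SHOULDER",
                            "SHOULDER_LEFT"),
    squat = c("HIP_LEFT", "KNEE_LEFT", "ANKLE_LEFT", "FOOT_LEFT",
              "HIP_RIGHT", "KNEE_RIGHT", "ANKLE_RIGHT", "FOOT_RIGHT")
  )
}

#' The shipped exercise catalog
#'
#' The default catalog contains 52 parameterized exercises: 29 in the
#' shoulder family (abduction, flexion and rotation raises per side, plus
#' isometric scapular-retraction holds) and 23 in the knee family (double-leg
#' squats plus per-side extension and protraction movements). Individual
#' prescriptions vary only in target magnitude and side, so entries are
#' systematic template instances; a physiotherapist would normally edit
#' targets and repetitions per patient via [load_catalog()].
#'
#' @param tolerance Name of the tolerance profile attached to every entry.
#' @return A tibble with one row per exercise: `id`, `name`, `family`,
#'   `movement`, `side`, `template`, `controlled_joints` (list-column),
#'   `target`, `target_unit`, `repetitions`, `series`, `tolerance`.
#' @export
#' @examples
#' nrow(default_catalog())
#' dplyr::count(default_catalog(), family)
default_catalog <- function(tolerance = "elderly") {
  entry <- function(family, movement, side, template, target, unit, reps) {
    tibble::tibble(
      family = family, movement = movement, side = side, template = template,
      target = target, target_unit = unit, repetitions = reps
    )
  }
  rows <- dplyr::bind_rows(
    # shoulder: 2 sides x 5 targets x 2 movements + 2 x 3 rotation + 3 holds
    tidyr::expand_grid(movement = c("abduction", "flexion"),
                       side = c("left", "right"),
                       target = c(70, 90, 110, 130, 150)) |>
      dplyr::mutate(family = "shoulder", template = "concentric_angle",
                    target_unit = "degrees", repetitions = 12),
    tidyr::expand_grid(movement = "rotation", side = c("left", "right"),
                       target = c(45, 60, 90)) |>
      dplyr::mutate(family = "shoulder", template = "concentric_angle",
                    target_unit = "degrees", repetitions = 10),
    tidyr::expand_grid(movement = "scapular_retraction", side = "both",
                       target = c(10, 20, 30)) |>
      dplyr::mutate(family = "shoulder", template = "isometric_hold",
                    target_unit = "seconds", repetitions = 10),
    # knee: 7 squats + 2 sides x 5 extension + 2 sides x 3 protraction
    tidyr::expand_grid(movement = "squat", side = "both",
                       target = c(160, 150, 140, 130, 120, 110, 100)) |>
      dplyr::mutate(family = "knee", template = "posture_constrained_squat",
                    target_unit = "degrees", repetitions = 10),
    tidyr::expand_grid(movement = "extension", side = c("left", "right"),
                       target = c(120, 130, 140, 150, 160)) |>
      dplyr::mutate(family = "knee", template = "concentric_angle",
                    target_unit = "degrees", repetitions = 12),
    tidyr::expand_grid(movement = "protraction", side = c("left", "right"),
                       target = c(100, 120, 140)) |>
      dplyr::mutate(family = "knee", template = "concentric_angle",
                    target_unit = "degrees", repetitions = 10)
  )
  cat <- rows |>
    dplyr::mutate(
      id = sprintf("%s_%02d", .data$family,
                   stats::ave(seq_len(nrow(rows)), rows$family,
                              FUN = seq_along)),
      name = sprintf("%s %s %s %g%s", .data$family, .data$movement,
                     .data$side, .data$target,
                     ifelse(.data$target_unit == "seconds", "s", "deg")),
      series = 3L,
      tolerance = tolerance,
      controlled_joints = purrr::map2(.data$movement, .data$side,
                                      controlled_joints_for)
    ) |>
    dplyr::select("id", "name", "family", "movement", "side", "template",
                  "controlled_joints", "target", "target_unit",
                  "repetitions", "series", "tolerance")
  validate_catalog(cat)
}

#' Validate a catalog tibble
#'
#' Checks every entry against the catalog invariants: positive target,
#' repetitions within 10 to 15, a known template, a resolvable tolerance
#' profile, controlled joints drawn from the 25-joint model and a family
#' consistent with those joints (shoulder exercises control arm/shoulder
#' joints, knee exercises leg joints).
#'
#' @param catalog A catalog tibble (see [default_catalog()]).
#' @return The validated catalog, invisibly unchanged.
#' @export
validate_catalog <- function(catalog) {
  need <- c("id", "name", "family", "movement", "side", "template",
            "controlled_joints", "target", "target_unit", "repetitions",
            "series", "tolerance")
  miss <- setdiff(need, names(catalog))
  if (length(miss) > 0) {
    abort(paste0("catalog is missing column(s): ",
                 paste(miss, collapse = ", ")),
          class = "exertrack_validation_error")
  }
  fail <- function(id, field, msg) {
    abort(sprintf("invalid catalog entry '%s', field `%s`: %s",
                  id, field, msg),
          class = "exertrack_validation_error")
  }
  arm_joints <- grep("SHOULDER|ELBOW|WRIST|HAND|THUMB|SPINE",
                     kinect_joints(), value = TRUE)
  leg_joints <- grep("HIP|KNEE|ANKLE|FOOT", kinect_joints(), value = TRUE)
  for (i in seq_len(nrow(catalog))) {
    e <- catalog[i, ]
    cj <- e$controlled_joints[[1]]
    if (!is.na(e$target) && e$target <= 0) {
      fail(e$id, "target", "must be positive")
    }
    if (e$repetitions < 10 || e$repetitions > 15) {
      fail(e$id, "repetitions", "must lie in [10, 15]")
    }
    if (!e$template %in% exercise_templates) {
      fail(e$id, "template", paste0("unknown template '", e$template, "'"))
    }
    if (!e$tolerance %in% c("elderly", "strict")) {
      fail(e$id, "tolerance", paste0("unknown profile '", e$tolerance, "'"))
    }
    if (length(setdiff(cj, kinect_joints())) > 0) {
      fail(e$id, "controlled_joints",
           paste0("unknown joint(s): ",
                  paste(setdiff(cj, kinect_joints()), collapse = ", ")))
    }
    ok_family <- switch(e$family,
      shoulder = all(cj %in% arm_joints),
      knee = all(cj %in% leg_joints),
      FALSE
    )
    if (!isTRUE(ok_family)) {
      fail(e$id, "family",
           "family must be shoulder/knee and consistent with controlled joints")
    }
  }
  invisible(catalog)
}

#' Read / write an exercise catalog
#'
#' Catalogs are human-editable YAML documents (versioned). `load_catalog()`
#' with `path = NULL` returns the shipped [default_catalog()]; an empty
#' document yields an empty catalog. Every loaded entry is validated and a
#' malformed entry is reported with its id and field.
#'
#' @param path Path to a catalog YAML file, or `NULL` for the shipped
#'   default.
#' @param catalog A catalog tibble to serialize.
#' @return `load_catalog()` returns a catalog tibble; `write_catalog()`
#'   returns `path` invisibly.
#' @export
load_catalog <- function(path = NULL) {
  if (is.null(path)) {
    return(default_catalog())
  }
  doc <- yaml::read_yaml(path)
  if (is.null(doc) || length(doc$exercises %||% list()) == 0) {
    return(empty_catalog())
  }
  cat <- purrr::map_dfr(doc$exercises, function(e) {
    tibble::tibble(
      id = e$id, name = e$name %||% e$id, family = e$family,
      movement = e$movement %||% NA_character_,
      side = e$side %||% "both", template = e$template,
      controlled_joints = list(unlist(e$controlled_joints)),
      target = as.numeric(e$target),
      target_unit = e$target_unit %||% "degrees",
      repetitions = as.integer(e$repetitions),
      series = as.integer(e$series %||% 3L),
      tolerance = e$tolerance %||% "elderly"
    )
  })
  validate_catalog(cat)
  cat
}

empty_catalog <- function() {
  default_catalog()[0, ]
}

#' @rdname load_catalog
#' @export
write_catalog <- function(catalog, path) {
  validate_catalog(catalog)
  doc <- list(
    format = "exertrack_catalog",
    version = 1L,
    exercises = purrr::map(seq_len(nrow(catalog)), function(i) {
      e <- catalog[i, ]
      list(id = e$id, name = e$name, family = e$family,
           movement = e$movement, side = e$side, template = e$template,
           controlled_joints = as.list(e$controlled_joints[[1]]),
           target = e$target, target_unit = e$target_unit,
           repetitions = e$repetitions, series = e$series,
           tolerance = e$tolerance)
    })
  )
  yaml::write_yaml(doc, path)
  invisible(path)
}
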