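#' Read and write frame-stream files
#'
#' The frame-stream file is a documented line-oriented text format: a header
#' line `#exertrack-frames v1 rate=<fps>`, then one frame per line —
#' the timestamp followed by 25 whitespace-separated records
#' `JOINT x y z` (metres, camera space: +y up, +z from the sensor toward
#' the user). All numbers are written with 6 decimals, and a write/read
#' round-trip is lossless at that precision. Malformed lines are reported
#' with their line number.
#'
#' @param path File path.
#' @param stream A `frame_stream`.
#' @return `read_frame_stream()` returns a `frame_stream`;
#'   `write_frame_stream()` returns `path` invisibly.
#' @export
#' @examples
#' fs <- simulate_static(body_model(), duration_s = 0.2)
#' p <- tempfile(fileext = ".txt")
#' write_frame_stream(fs, p)
#' fs2 <- read_frame_stream(p)
write_frame_stream <- function(stream, path) {
  stopifnot(is_frame_stream(stream))
  arr <- stream_arrays(stream)
  joints <- kinect_joints()
  lines <- vapply(seq_along(arr$time), function(i) {
    recs <- vapply(joints, function(j) {
      sprintf("%s %.6f %.6f %.6f", j,
              arr$pos[i, j, 1], arr$pos[i, j, 2], arr$pos[i, j, 3])
    }, "")
    paste(sprintf("%.6f", arr$time[i]), paste(recs, collapse = " "))
  }, "")
  writeLines(c(sprintf("#exertrack-frames v1 rate=%g", nominal_rate(stream)),
               lines), path)
  invisible(path)
}

#' @rdname write_frame_stream
#' @export
read_frame_stream <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0 ||
      !grepl("^#exertrack-frames v1 rate=", lines[1])) {
    abort("missing or unrecognized frame-stream header",
          class = "exertrack_format_error")
  }
  rate <- as.numeric(sub("^#exertrack-frames v1 rate=", "", lines[1]))
  if (is.na(rate) || rate <= 0) {
    abort("header declares an invalid rate", class = "exertrack_format_error")
  }
  body_lines <- lines[-1]
  body_lines <- body_lines[nzchar(trimws(body_lines))]
  frames <- lapply(seq_along(body_lines), function(li) {
    tok <- strsplit(trimws(body_lines[li]), "\\s+")[[1]]
    if (length(tok) != 1 + 25 * 4) {
      abort(sprintf(
        "format error at line %d: expected a timestamp and 25 joint records, found %d tokens",
        li + 1, length(tok)),
        class = "exertrack_format_error")
    }
    ts <- suppressWarnings(as.numeric(tok[1]))
    jn <- tok[seq(2, length(tok), by = 4)]
    xs <- suppressWarnings(as.numeric(tok[seq(3, length(tok), by = 4)]))
    ys <- suppressWarnings(as.numeric(tok[seq(4, length(tok), by = 4)]))
    zs <- suppressWarnings(as.numeric(tok[seq(5, length(tok), by = 4)]))
    if (anyNA(c(ts, xs, ys, zs))) {
      abort(sprintf("format error at line %d: non-numeric coordinate",
                    li + 1),
            class = "exertrack_format_error")
    }
    bad <- setdiff(jn, kinect_joints())
    if (length(bad) > 0 || anyDuplicated(jn)) {
      abort(sprintf("format error at line %d: invalid joint set", li + 1),
            class = "exertrack_format_error")
    }
    tibble::tibble(time = ts, joint = jn, x = xs, y = ys, z = zs)
  })
  frame_stream(dplyr::bind_rows(frames), nominal_rate = rate)
}

#' Read and write session-record CSV files
#'
#' Session results are stored as CSV with the header
#' `participant_id,age,gender,exercise_id,session,average_angle` — the same
#' shape as a deposited physical-performance table (one average angle per
#' participant, exercise and session). Angles are formatted with exactly 5
#' decimal places.
#'
#' @param records A session-record data frame.
#' @param path File path.
#' @return `read_session_csv()` returns a tibble of records;
#'   `write_session_csv()` returns `path` invisibly.
#' @export
#' @examples
#' tab <- simulate_study(seed = 1)
#' p <- tempfile(fileext = ".csv")
#' write_session_csv(tab, p)
#' identical(read_session_csv(p)$average_angle, tab$average_angle)
write_session_csv <- function(records, path) {
  need <- c("participant_id", "age", "gender", "exercise_id", "session",
            "average_angle")
  miss <- setdiff(need, names(records))
  if (length(miss) > 0) {
    abort(paste0("session records are missing column(s): ",
                 paste(miss, collapse = ", ")),
          class = "exertrack_format_error")
  }
  out <- records[need]
  out$average_angle <- sprintf("%.5f", round5(out$average_angle))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_session_csv
#' @export
read_session_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("participant_id", "age", "gender", "exercise_id", "session",
            "average_angle")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    abort(paste0("session CSV is missing column(s): ",
                 paste(miss, collapse = ", ")),
          class = "exertrack_format_error")
  }
  tibble::as_tibble(df) |>
    dplyr::mutate(session = as.integer(.data$session),
                  average_angle = as.numeric(.data$average_angle))
}
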