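# Nonparametric progress statistics. The tests are implemented here rather
# than delegated so that the small-sample branches are exact by full
# enumeration (all label arrangements / sign assignments) with midrank tie
# handling, and the large-sample branches use the normal approximation with
# the usual tie corrections. stats::wilcox.test agrees on the exact branch
# and serves as an independent cross-check in the test suite.

midranks <- function(x) rank(x, ties.method = "average")

tie_sizes <- function(r) {
  t <- table(r)
  as.numeric(t[t > 1])
}

two_sided <- function(lo, hi) min(1, 2 * min(lo, hi))

#' Mann-Whitney U test
#'
#' Rank-sum test of whether two independent samples can be assumed to come
#' from the same distribution. `U` is the statistic for `x` with midrank
#' ties. The p-value is exact — by enumeration of all `choose(nx+ny, nx)`
#' group labelings — when `nx + ny <= 12` and there are no ties, and uses
#' the normal approximation with tie correction otherwise. Two-sided
#' throughout.
#'
#' @param x,y Numeric samples (both nonempty).
#' @param exact Force (`TRUE`) or forbid (`FALSE`) the exact branch;
#'   `NULL` (default) decides by sample size and ties.
#' @return A `rank_test` object with `statistic` (U), `p_value`, `method`
#'   and sample sizes; see [tidy()].
#' @export
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6))$p_value  # exact, 0.1
mann_whitney_u <- function(x, y, exact = NULL) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) == 0 || length(y) == 0) {
    abort("both samples must be nonempty", class = "exertrack_input_error")
  }
  nx <- length(x); ny <- length(y); n <- nx + ny
  r <- midranks(c(x, y))
  u <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  ties <- tie_sizes(r)
  do_exact <- exact %||% (n <= 12 && length(ties) == 0)
  if (do_exact && length(ties) > 0) do_exact <- FALSE
  if (do_exact) {
    # null distribution of U over all label arrangements
    combs <- combn(n, nx)
    u_null <- colSums(matrix(r[combs], nrow = nx)) - nx * (nx + 1) / 2
    p <- two_sided(mean(u_null <= u), mean(u_null >= u))
    method <- "exact enumeration"
  } else {
    mu <- nx * ny / 2
    tie_term <- if (length(ties) > 0) sum(ties^3 - ties) / (n * (n - 1)) else 0
    sigma2 <- nx * ny / 12 * ((n + 1) - tie_term)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (u - mu) / sqrt(sigma2)
      p <- 2 * pnorm(-abs(z))
    }
    method <- "normal approximation with tie correction"
  }
  structure(list(
    statistic = u, p_value = p, method = method,
    test = "Mann-Whitney U", n_x = nx, n_y = ny, exact = do_exact
  ), class = "rank_test")
}

#' Wilcoxon signed-rank test
#'
#' Paired-series test on the signed differences: zero differences are
#' discarded, tied magnitudes receive midranks, and `W` is the sum of the
#' ranks of the positive differences. The p-value is exact — by enumeration
#' of all `2^n` sign assignments — for `n <= 12` retained differences, and
#' uses the normal approximation with tie correction otherwise. Two-sided.
#'
#' @param diffs Numeric paired differences with at least one nonzero value.
#' @param exact As in [mann_whitney_u()].
#' @return A `rank_test` object with `statistic` (W) and `p_value`.
#' @export
#' @examples
#' wilcoxon_signed_rank(c(1, 2, 3, 4, 5))$p_value  # 2/32
wilcoxon_signed_rank <- function(diffs, exact = NULL) {
  d <- as.numeric(diffs)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    abort("all paired differences are zero: signed-rank test is degenerate",
          class = "exertrack_degenerate_error")
  }
  r <- midranks(abs(d))
  w <- sum(r[d > 0])
  ties <- tie_sizes(r)
  do_exact <- exact %||% (n <= 12)
  if (do_exact) {
    # null distribution of W over all sign assignments of the ranks
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    w_null <- as.numeric(signs %*% r)
    p <- two_sided(mean(w_null <= w), mean(w_null >= w))
    method <- "exact enumeration"
  } else {
    mu <- n * (n + 1) / 4
    tie_term <- if (length(ties) > 0) sum(ties^3 - ties) / 48 else 0
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - tie_term
    z <- (w - mu) / sqrt(sigma2)
    p <- 2 * pnorm(-abs(z))
    method <- "normal approximation with tie correction"
  }
  structure(list(
    statistic = w, p_value = p, method = method,
    test = "Wilcoxon signed-rank", n = n, exact = do_exact
  ), class = "rank_test")
}

#' Spearman rank correlation
#'
#' Nonparametric rank correlation: the Pearson correlation of the midranks,
#' with a two-sided p-value from the t approximation with `n - 2` degrees of
#' freedom. Used to relate perceived benefit (survey scores) to measured
#' benefit (average angles).
#'
#' @param x,y Numeric samples of equal length >= 3; neither constant.
#' @return A `rank_test` object with `statistic` (rho) and `p_value`.
#' @export
spearman_rho <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  n <- length(x)
  if (n != length(y) || n < 3) {
    abort("`x` and `y` must have equal length >= 3",
          class = "exertrack_input_error")
  }
  rx <- midranks(x); ry <- midranks(y)
  if (sd(rx) == 0 || sd(ry) == 0) {
    abort("correlation undefined for a constant sample",
          class = "exertrack_degenerate_error")
  }
  rho <- stats::cor(rx, ry)
  p <- if (abs(rho) >= 1 - 1e-15) {
    0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * pt(-abs(tstat), df = n - 2)
  }
  structure(list(
    statistic = rho, p_value = p, method = "t approximation",
    test = "Spearman rank correlation", n = n, exact = FALSE
  ), class = "rank_test")
}

#' @export
print.rank_test <- function(x, ...) {
  cat(sprintf("<%s> statistic = %.6g, p = %.4g (%s)\n",
              x$test, x$statistic, x$p_value, x$method))
  invisible(x)
}

#' Percentile-whisker boxplot summary
#'
#' Five-number summary with whiskers at the 10th and 90th percentiles;
#' values beyond the whiskers are counted as extreme points, matching the
#' boxplot convention used for the session score distributions.
#'
#' @param x A numeric sample.
#' @return A one-row tibble: `n`, `whisker_low` (10th percentile), `q1`,
#'   `median`, `q3`, `whisker_high` (90th percentile), `n_outliers`,
#'   `outliers` (list-column).
#' @export
boxplot_summary <- function(x) {
  x <- as.numeric(x[!is.na(x)])
  q <- quantile(x, c(0.1, 0.25, 0.5, 0.75, 0.9), names = FALSE)
  out <- x[x < q[1] | x > q[5]]
  tibble::tibble(
    n = length(x),
    whisker_low = q[1], q1 = q[2], median = q[3], q3 = q[4],
    whisker_high = q[5],
    n_outliers = length(out), outliers = list(out)
  )
}

#' Session-progress report
#'
#' Mirrors the study's evaluation methodology on a table of session records
#' (`participant_id`, `age`, `gender`, `exercise_id`, `session`,
#' `average_angle`): per group and exercise it computes a
#' [boxplot_summary()] for every session, contrasts the selected session
#' pairs within each group with both the Mann-Whitney U test and the
#' Wilcoxon signed-rank test (paired by participant), and compares adjacent
#' groups in the same session with the Mann-Whitney U test only — the
#' signed-rank test does not apply across independent groups. A degenerate
#' Wilcoxon contrast (all paired differences zero) is reported as a note,
#' not a failure, as is a requested session absent from the records.
#'
#' @param records A session-record data frame (see [simulate_study()]).
#' @param group_by `"age"` (grouping by the study age ranges) or
#'   `"gender"`.
#' @param contrasts List of session pairs to contrast within groups
#'   (default sessions (2,4), (2,6), (4,6)).
#' @return A `progress_report`: list with tibbles `summaries`,
#'   `within_group` and `between_group`; see [autoplot()], [glance()].
#' @export
#' @examples
#' rep <- progress_report(simulate_study(seed = 1))
#' head(rep$within_group)
progress_report <- function(records, group_by = c("age", "gender"),
                            contrasts = list(c(2, 4), c(2, 6), c(4, 6))) {
  group_by <- match.arg(group_by)
  need <- c("participant_id", "exercise_id", "session", "average_angle")
  miss <- setdiff(need, names(records))
  if (length(miss) > 0) {
    abort(paste0("records are missing column(s): ",
                 paste(miss, collapse = ", ")),
          class = "exertrack_format_error")
  }
  records <- tibble::as_tibble(records)
  records$group <- if (group_by == "age") {
    as.character(age_group(records$age))
  } else {
    records$gender
  }

  summaries <- records |>
    dplyr::group_by(.data$group, .data$exercise_id, .data$session) |>
    dplyr::reframe(boxplot_summary(.data$average_angle))

  have_sessions <- sort(unique(records$session))
  cells <- dplyr::distinct(records, .data$group, .data$exercise_id)

  within <- purrr::map_dfr(seq_len(nrow(cells)), function(ci) {
    cell <- records |>
      dplyr::filter(.data$group == cells$group[ci],
                    .data$exercise_id == cells$exercise_id[ci])
    purrr::map_dfr(contrasts, function(cp) {
      base <- tibble::tibble(
        group = cells$group[ci], exercise_id = cells$exercise_id[ci],
        session_a = cp[1], session_b = cp[2]
      )
      if (!all(cp %in% have_sessions)) {
        return(dplyr::mutate(base, mw_u = NA_real_, mw_p = NA_real_,
                             wilcoxon_w = NA_real_, wilcoxon_p = NA_real_,
                             note = sprintf("session(s) %s missing",
                                            paste(setdiff(cp, have_sessions),
                                                  collapse = ","))))
      }
      a <- cell[cell$session == cp[1], ]
      b <- cell[cell$session == cp[2], ]
      mw <- mann_whitney_u(a$average_angle, b$average_angle)
      paired <- dplyr::inner_join(
        a[, c("participant_id", "average_angle")],
        b[, c("participant_id", "average_angle")],
        by = "participant_id", suffix = c("_a", "_b"))
      d <- paired$average_angle_b - paired$average_angle_a
      if (all(d == 0)) {
        return(dplyr::mutate(base, mw_u = mw$statistic, mw_p = mw$p_value,
                             wilcoxon_w = NA_real_, wilcoxon_p = NA_real_,
                             note = "signed-rank degenerate: all paired differences zero"))
      }
      wx <- wilcoxon_signed_rank(d)
      dplyr::mutate(base, mw_u = mw$statistic, mw_p = mw$p_value,
                    wilcoxon_w = wx$statistic, wilcoxon_p = wx$p_value,
                    note = NA_character_)
    })
  })

  groups <- if (group_by == "age") {
    levels(age_group(records$age))
  } else {
    sort(unique(records$gender))
  }
  groups <- groups[groups %in% records$group]
  pairs <- if (length(groups) >= 2) {
    lapply(seq_len(length(groups) - 1), function(i) groups[i + 0:1])
  } else {
    list()
  }
  between <- purrr::map_dfr(pairs, function(gp) {
    purrr::map_dfr(unique(records$exercise_id), function(ex) {
      purrr::map_dfr(have_sessions, function(s) {
        a <- records$average_angle[records$group == gp[1] &
                                     records$exercise_id == ex &
                                     records$session == s]
        b <- records$average_angle[records$group == gp[2] &
                                     records$exercise_id == ex &
                                     records$session == s]
        mw <- mann_whitney_u(a, b)
        tibble::tibble(group_a = gp[1], group_b = gp[2], exercise_id = ex,
                       session = s, mw_u = mw$statistic, mw_p = mw$p_value)
      })
    })
  })

  structure(list(
    summaries = summaries,
    within_group = within,
    between_group = between,
    group_by = group_by,
    contrasts = contrasts
  ), class = "progress_report")
}

#' @export
print.progress_report <- function(x, ...) {
  cat("<progress_report> grouped by", x$group_by, "\n")
  cat("  summaries:", nrow(x$summaries), "group x exercise x session cells\n")
  cat("  within-group contrasts:", nrow(x$within_group), "\n")
  cat("  between-group comparisons:", nrow(x$between_group), "\n")
  invisible(x)
}

#' Write a progress report to CSV files
#'
#' @param report A `progress_report`.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_report_csv <- function(report, dir) {
  stopifnot(inherits(report, "progress_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(dplyr::select(report$summaries, -dplyr::any_of("outliers")),
                   file.path(dir, "summaries.csv"), row.names = FALSE)
  utils::write.csv(report$within_group,
                   file.path(dir, "within_group_tests.csv"),
                   row.names = FALSE)
  utils::write.csv(report$between_group,
                   file.path(dir, "between_group_tests.csv"),
                   row.names = FALSE)
  invisible(dir)
}
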