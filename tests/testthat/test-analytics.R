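test_that("Mann-Whitney U matches its exact examples", {
  r <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 0.1)   # 2/20 label arrangements as extreme
  expect_true(r$exact)
  # identical multisets: U = n^2 / 2 under midranks
  r2 <- mann_whitney_u(c(5, 7, 7, 9), c(5, 7, 7, 9))
  expect_equal(r2$statistic, 16 / 2)
  expect_error(mann_whitney_u(numeric(0), 1:3),
               class = "exertrack_input_error")
})

test_that("Mann-Whitney exact branch agrees with the reference oracle", {
  set.seed(55)
  for (i in 1:25) {
    nx <- sample(2:4, 1); ny <- sample(2:3, 1)
    x <- round(rnorm(nx), 3); y <- round(rnorm(ny), 3)
    if (anyDuplicated(c(x, y))) next
    got <- mann_whitney_u(x, y)
    ref <- stats::wilcox.test(x, y, exact = TRUE, correct = FALSE)
    expect_equal(got$statistic, unname(ref$statistic))
    expect_equal(got$p_value, unname(ref$p.value))
  }
})

test_that("Wilcoxon signed-rank matches its exact examples", {
  r <- wilcoxon_signed_rank(c(1, 2, 3, 4, 5))
  expect_equal(r$statistic, 15)
  expect_equal(r$p_value, 2 / 32)
  # antisymmetric differences sit at the null centre W = n(n+1)/4
  d <- c(1, -1, 2, -2, 3, -3)
  expect_equal(wilcoxon_signed_rank(d)$statistic, 6 * 7 / 4)
  # zeros are discarded before ranking
  expect_equal(wilcoxon_signed_rank(c(0, 0, 1, 2, 3))$p_value,
               wilcoxon_signed_rank(c(1, 2, 3))$p_value)
  expect_error(wilcoxon_signed_rank(c(0, 0)),
               class = "exertrack_degenerate_error")
})

test_that("Wilcoxon exact branch agrees with the reference oracle", {
  set.seed(66)
  for (i in 1:25) {
    n <- sample(4:10, 1)
    d <- round(rnorm(n), 3)
    d <- d[d != 0]
    if (anyDuplicated(abs(d)) || length(d) < 2) next
    got <- wilcoxon_signed_rank(d)
    ref <- stats::wilcox.test(d, exact = TRUE, correct = FALSE)
    expect_equal(got$statistic, unname(ref$statistic))
    expect_equal(got$p_value, unname(ref$p.value))
  }
})

test_that("large-sample branches use the tie-corrected normal approximation", {
  set.seed(77)
  x <- round(rnorm(30), 1); y <- round(rnorm(25, mean = 0.6), 1)
  got <- mann_whitney_u(x, y)
  ref <- stats::wilcox.test(x, y, exact = FALSE, correct = FALSE)
  expect_false(got$exact)
  expect_equal(got$p_value, unname(ref$p.value), tolerance = 1e-12)
  d <- round(rnorm(30, 0.4), 1); d <- d[d != 0]
  got2 <- wilcoxon_signed_rank(d)
  ref2 <- stats::wilcox.test(d, exact = FALSE, correct = FALSE)
  expect_equal(got2$p_value, unname(ref2$p.value), tolerance = 1e-12)
})

test_that("Spearman rho handles perfect monotone association and ties", {
  expect_equal(spearman_rho(1:6, c(10, 20, 30, 40, 50, 60))$statistic, 1)
  expect_equal(spearman_rho(1:6, -(1:6))$statistic, -1)
  # midrank oracle with ties
  set.seed(88)
  for (i in 1:10) {
    x <- sample(1:5, 8, replace = TRUE)
    y <- sample(1:5, 8, replace = TRUE)
    if (sd(x) == 0 || sd(y) == 0) next
    got <- spearman_rho(x, y)
    oracle <- stats::cor(rank(x), rank(y))
    expect_equal(got$statistic, oracle, tolerance = 1e-12)
    ref <- suppressWarnings(
      stats::cor.test(x, y, method = "spearman", exact = FALSE))
    expect_equal(got$statistic, unname(ref$estimate), tolerance = 1e-12)
  }
  expect_error(spearman_rho(rep(1, 5), 1:5),
               class = "exertrack_degenerate_error")
})

test_that("rank tests are invariant under strictly monotone transforms", {
  set.seed(101)
  x <- rnorm(8); y <- rnorm(9, 0.5)
  f <- function(v) exp(v) + v^3 / 10
  a <- mann_whitney_u(x, y); b <- mann_whitney_u(f(x), f(y))
  expect_equal(a$statistic, b$statistic)
  expect_equal(a$p_value, b$p_value)
  r1 <- spearman_rho(x, y[1:8]); r2 <- spearman_rho(f(x), f(y[1:8]))
  expect_equal(r1$statistic, r2$statistic)
})

test_that("boxplot summaries put whiskers at the 10th and 90th percentiles", {
  set.seed(9)
  x <- rnorm(200)
  s <- boxplot_summary(x)
  expect_equal(s$whisker_low, unname(quantile(x, 0.1)))
  expect_equal(s$whisker_high, unname(quantile(x, 0.9)))
  expect_true(s$whisker_low <= s$q1 && s$q1 <= s$median &&
                s$median <= s$q3 && s$q3 <= s$whisker_high)
  expect_equal(s$n_outliers, sum(x < s$whisker_low | x > s$whisker_high))
})

test_that("progress_report contrasts improve on a strongly improving study", {
  tab <- simulate_study(study_config(), seed = 3)
  rep <- progress_report(tab, group_by = "age")
  expect_true(all(rep$within_group$mw_p < 0.01))
  expect_true(all(rep$within_group$wilcoxon_p < 0.01))
  expect_true(all(rep$between_group$mw_p < 0.001))
  expect_equal(nrow(rep$within_group), 3 * 2 * 3)  # groups x exercises x pairs
  g <- glance(rep)
  expect_equal(g$n_groups, 3)
  expect_lt(g$max_within_p, 0.01)
  # gender grouping compares the two genders per session
  repg <- progress_report(tab, group_by = "gender")
  expect_equal(unique(repg$summaries$group), c("F", "M"))
})

test_that("progress_report degrades gracefully on sparse input", {
  tab <- simulate_study(study_config(), seed = 4)
  single <- tab[tab$session == 1, ]
  rep <- progress_report(single)
  expect_true(all(!is.na(rep$within_group$note)))
  expect_true(all(is.na(rep$within_group$mw_p)))
  expect_gt(nrow(rep$summaries), 0)
  # two identical sessions: the signed-rank contrast is noted as degenerate
  dup <- dplyr::bind_rows(
    dplyr::mutate(single, session = 2),
    dplyr::mutate(single, session = 6))
  rep2 <- progress_report(dup, contrasts = list(c(2, 6)))
  expect_true(all(grepl("degenerate", rep2$within_group$note)))
  expect_true(all(is.na(rep2$within_group$wilcoxon_p)))
  expect_true(all(!is.na(rep2$within_group$mw_p)))
})

test_that("autoplot renders the report without error", {
  tab <- simulate_study(study_config(), seed = 5)
  p <- autoplot(progress_report(tab))
  expect_s3_class(p, "ggplot")
  expect_no_error(ggplot2::ggplot_build(p))
})
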