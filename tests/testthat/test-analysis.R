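test_that("pearson correlation matches the textbook sum formula", {
  x <- c(1, 2, 3, 4); y <- c(1, 3, 2, 5)
  got <- pearson_correlation(x, y)
  exp <- oracle_pearson(x, y)
  expect_equal(got$r, exp$r, tolerance = 1e-10)
  expect_equal(got$p, exp$p, tolerance = 1e-10)
  expect_equal(got$df, 2)

  expect_equal(pearson_correlation(1:5, 2 * (1:5) + 1)$r, 1)
  expect_equal(pearson_correlation(1:5, -(1:5))$r, -1)
  expect_error(pearson_correlation(1:5, rep(3, 5)), "constant")
  expect_error(pearson_correlation(1:2, 2:3), "at least 3")
})

test_that("two-group t matches the hand-computed pooled formula", {
  x <- c(3.1, 4.5, 2.8, 5.0, 3.9); y <- c(5.2, 6.1, 4.8, 5.5)
  got <- two_group_t(x, y)
  exp <- oracle_pooled_t(x, y)
  expect_equal(got$statistic, exp$t, tolerance = 1e-10)
  expect_equal(got$df, exp$df)
  expect_equal(got$p, exp$p, tolerance = 1e-10)

  same <- two_group_t(c(1, 2, 3), c(3, 2, 1))
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)

  # Welch variant carries fractional df
  w <- two_group_t(x, y, pooled = FALSE)
  expect_equal(w$statistic, unname(stats::t.test(x, y)$statistic))
  expect_lt(abs(w$df - unname(stats::t.test(x, y)$parameter)), 1e-12)
})

test_that("zero-variance groups yield a degenerate statistic with a warning", {
  expect_warning(res <- two_group_t(c(0, 0, 0, 0), c(1, 1, 1, 1)), "degenerate")
  expect_true(is.infinite(res$statistic))
  expect_equal(res$p, 0)
  expect_warning(res0 <- two_group_t(c(2, 2), c(2, 2)), "degenerate")
  expect_equal(res0$statistic, 0)
  expect_equal(res0$p, 1)
})

test_that("chi-square matches the direct sum over (O-E)^2/E", {
  tab <- matrix(c(10, 20, 20, 10), 2)
  got <- suppressWarnings(chi_square_independence(tab))
  exp <- oracle_chisq(tab)
  expect_equal(got$statistic, exp$statistic, tolerance = 1e-10)
  expect_equal(got$df, exp$df)
  expect_equal(got$p, exp$p, tolerance = 1e-10)

  # identical row proportions: no association
  flat <- matrix(c(10, 20, 30, 60), 2)
  expect_equal(chi_square_independence(flat)$statistic, 0)

  # df = (r-1)(c-1)
  wide <- matrix(c(8, 9, 12, 11, 10, 9, 7, 14), 2)
  expect_equal(chi_square_independence(wide)$df, 3)

  expect_error(chi_square_independence(matrix(c(0, 0, 5, 7), 2)), "margins")
  expect_warning(chi_square_independence(matrix(c(2, 3, 4, 5), 2)), "below 5")
})

test_that("type-I error of the pooled t-test is near nominal under the null", {
  set.seed(20260920)
  reps <- 2000
  hits <- 0L
  for (i in seq_len(reps)) {
    x <- stats::rnorm(12); y <- stats::rnorm(12)
    if (two_group_t(x, y)$p < 0.05) hits <- hits + 1L
  }
  rate <- hits / reps
  # three Monte-Carlo standard errors around 0.05
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / reps))
})

test_that("factor adjustment removes group offsets and preserves the grand mean", {
  # two schools offset by a constant
  x <- c(50, 55, 60, 70, 75, 80)
  school <- c("A", "A", "A", "B", "B", "B")
  adj <- adjust_for_factors(x, school)
  expect_equal(mean(adj), mean(x))
  expect_equal(mean(adj[school == "A"]), mean(adj[school == "B"]))
  # zero covariance with the factor indicator
  expect_lt(abs(stats::cov(adj, as.numeric(school == "A"))), 1e-10)
  # idempotent
  expect_equal(adjust_for_factors(adj, school), adj)
  # single school + classroom: centering no-op returns the data unchanged
  expect_equal(adjust_for_factors(x, rep("A", 6), rep("c1", 6)), x)
})

test_that("school+classroom adjustment handles nesting and singletons", {
  set.seed(5)
  school <- rep(c("A", "B"), each = 6)
  classroom <- paste0(school, rep(c(1, 2), times = 6))
  x <- stats::rnorm(12, 60, 5) + ifelse(school == "B", 8, 0)
  adj <- adjust_for_factors(x, school, classroom)
  expect_equal(mean(adj), mean(x))
  expect_lt(abs(mean(adj[school == "A"]) - mean(adj[school == "B"])), 1e-10)

  expect_warning(
    adjust_for_factors(c(1, 2, 3), c("A", "A", "B")),
    "single observation"
  )

  out <- validate_outcomes(tibble::tibble(
    parent_id = paste0("p", 1:12), school = school, classroom = classroom,
    treatment = "control", bmi_percentile_t0 = x
  ))
  adj_tbl <- adjust_bmi_percentile(out)
  expect_equal(adj_tbl$bmi_percentile_t0, adj, ignore_attr = TRUE)
})

test_that("split-plot repeated measures matches the closed-form oracle", {
  set.seed(99)
  n <- 10
  group <- rep(c("pd", "non_pd"), each = n / 2)
  baseline <- stats::rnorm(n, 55, 6)
  followup <- baseline + stats::rnorm(n, 1, 2)
  got <- repeated_measures_by_group(baseline, followup, group)
  exp <- oracle_split_plot(baseline, followup, group)
  eff <- function(e) got$effects[got$effects$effect == e, ]
  expect_equal(eff("group")$F, unname(exp$F_group), tolerance = 1e-10)
  expect_equal(eff("group")$p, unname(exp$p_group), tolerance = 1e-10)
  expect_equal(eff("time")$F, unname(exp$F_time), tolerance = 1e-10)
  expect_equal(eff("group:time")$F, unname(exp$F_gt), tolerance = 1e-10)
  expect_equal(eff("group:time")$p, unname(exp$p_gt), tolerance = 1e-10)
})

test_that("repeated measures recovers constructed group and time effects", {
  set.seed(17)
  n <- 16
  group <- rep(c("a", "b"), each = n / 2)
  subj <- stats::rnorm(n, 50, 4)
  # identical noise pattern in both groups keeps the cell-mean contrast
  # (hence the interaction) at zero by construction
  jitter <- rep(stats::rnorm(n / 2, 0, 0.5), 2)

  # group B offset by +8, flat over time: group effect, no interaction
  base1 <- subj + ifelse(group == "b", 8, 0)
  res1 <- repeated_measures_by_group(base1, base1 + jitter, group)
  m1 <- tapply(res1$means$mean, res1$means$group, mean)
  expect_equal(unname(m1["b"] - m1["a"]), 8, tolerance = 0.5)
  expect_gt(res1$effects$p[res1$effects$effect == "group:time"], 0.2)

  # equal time shift in both groups: time effect, no interaction
  res2 <- repeated_measures_by_group(subj, subj + 5 + jitter, group)
  expect_lt(res2$effects$p[res2$effects$effect == "time"], 1e-6)
  expect_gt(res2$effects$p[res2$effects$effect == "group:time"], 0.2)

  # no change, no difference: everything null
  res3 <- repeated_measures_by_group(subj, subj + jitter, group)
  expect_gt(res3$effects$p[res3$effects$effect == "group:time"], 0.05)

  expect_error(repeated_measures_by_group(1:4, 1:4, c("a", "a", "a", "b")),
               "at least 2")
  expect_error(repeated_measures_by_group(1:4, 1:4, rep("a", 4)),
               "two levels")
})

test_that("analyze_scores assembles the report blocks on synthetic data", {
  cat8 <- build_default_catalogs()
  sim <- generate_cohort(
    simulation_config(seed = 21, n_parents_per_arm = 12, bmi_dependence = -0.5),
    cat8
  )
  s <- score_cohort(sim$participation, cat8, outcomes = sim$outcomes)
  rep <- analyze_scores(s)
  expect_named(rep$summary, c("overall", "by_activity"))
  expect_lt(rep$bmi_correlation$pei$r, 0)
  expect_s3_class(rep$pd_intensity, "group_comparison")
  # PD parents are, by construction, the more intensely engaged
  expect_gt(rep$pd_intensity$mean[1], rep$pd_intensity$mean[2])
  expect_true(all(vapply(rep$pd_by_activity, function(b)
    is.null(b) || b$df == 1, logical(1))))
  expect_s3_class(rep$bmi_change_by_pd, "repeated_measures_result")
})
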