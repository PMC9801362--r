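test_that("normality routing has the expected operating characteristics", {
  # type-I error of the Shapiro-Wilk routing ~5%: >=90% of Gaussian samples
  # at n = 500 are called normal
  set.seed(41)
  calls <- vapply(1:100, function(i) {
    assess_normality(rnorm(500))$normal
  }, TRUE)
  expect_gte(mean(calls), 0.90)
  # heavy-tailed lognormal at n = 500: power ~1
  set.seed(42)
  expect_false(assess_normality(rlnorm(500, sdlog = 1))$normal)
  # constant sample: degenerate, routed non-normal
  res <- assess_normality(rep(1.5, 10))
  expect_false(res$normal)
  expect_true(res$degenerate)
  expect_error(assess_normality(c(1, 2)), "at least 3")
})

test_that("two-group comparison routes and flags correctly", {
  set.seed(43)
  x <- rnorm(40)
  same <- compare_two_groups(x, x)
  expect_equal(same$test, "t")
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)

  # skewed data routes to Mann-Whitney
  set.seed(44)
  a <- rlnorm(60, sdlog = 1.2)
  b <- rlnorm(60, sdlog = 1.2) * 3
  res <- compare_two_groups(a, b)
  expect_equal(res$test, "mann_whitney")
  expect_lt(res$p, 0.05)
  expect_error(compare_two_groups(c(1, 2), c(1, 2, 3)), "at least 3")
})

test_that("leg share separates synthetic cases and controls; arm share does not", {
  coh <- generate_cohort(default_config(), n_cases = 74, seed = 42)
  m <- match_controls(coh[coh$group == "case", ],
                      coh[coh$group == "control", ])
  panel <- compute_index_panel(cohort_table(m))
  is_case <- panel$group == "case"
  thr <- bonferroni_threshold(0.05, 27)
  legs <- compare_two_groups(panel$fm_share_legs[is_case],
                             panel$fm_share_legs[!is_case], n_tests = 27)
  expect_lt(legs$p, thr)
  arms <- compare_two_groups(panel$fm_share_arms[is_case],
                             panel$fm_share_arms[!is_case], n_tests = 27)
  expect_gt(arms$p, thr)
})

test_that("multi-group comparison routes, excludes small groups, posthocs", {
  set.seed(102)  # fixture precondition: the draw must look Gaussian
  x <- rnorm(30)
  res <- compare_multi_groups(c(x, x, x),
                              rep(c("a", "b", "c"), each = 30))
  expect_equal(res$test, "anova")
  expect_equal(res$statistic, 0, tolerance = 1e-12)
  expect_equal(res$p, 1, tolerance = 1e-12)

  # fixture precondition: all three draws must themselves look Gaussian
  set.seed(101)
  vals <- c(rnorm(30, 0), rnorm(30, 0), rnorm(30, 5))
  grp <- rep(c("a", "b", "c"), each = 30)
  res <- compare_multi_groups(vals, grp)
  expect_equal(res$test, "anova")
  expect_lt(res$p, 0.001)
  sig <- res$posthoc$significant
  names(sig) <- res$posthoc$comparison
  expect_true(sig[["c-a"]] && sig[["c-b"]])
  expect_false(sig[["b-a"]])

  # a group of n = 2 is excluded before testing (min_group_size = 5)
  vals2 <- c(vals, c(1, 2))
  grp2 <- c(grp, "d", "d")
  res2 <- compare_multi_groups(vals2, grp2, min_group_size = 5)
  expect_equal(res2$excluded, "d")
  expect_false("d" %in% res2$groups$group)

  expect_error(
    compare_multi_groups(c(rnorm(10), rnorm(10), 1, 2),
                         c(rep("a", 10), rep("b", 10), "c", "c")),
    "fewer than 3 eligible groups")
})

test_that("Bonferroni threshold is alpha/n and exact under multiplication", {
  expect_equal(sprintf("%.5f", bonferroni_threshold(0.05, 27)), "0.00185")
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(bonferroni_threshold(0.01, 4), 0.0025)
  for (n in c(1, 5, 27, 100)) {
    expect_identical(bonferroni_threshold(0.05, n) * n, 0.05)
  }
  expect_error(bonferroni_threshold(0, 5), "alpha")
  expect_error(bonferroni_threshold(0.05, 0), "n_tests")
})

test_that("correlation with stage routes and reports r-squared", {
  res <- correlate_index_with_stage(c(1, 2, 3, 4, 2.5, 3.5),
                                    c(1, 2, 3, 4, 2, 3))
  expect_equal(res$r2, res$r^2)

  perfect <- correlate_index_with_stage(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(perfect$r, 1)
  expect_equal(perfect$r2, 1)

  expect_error(correlate_index_with_stage(c(1, 1, 1), c(1, 2, 3)),
               "zero variance")

  # null correlation at n = 72: |r| < 0.3 in >= 95% of replicates
  set.seed(47)
  small <- vapply(1:100, function(i) {
    r <- correlate_index_with_stage(rnorm(72), sample(1:4, 72, TRUE))$r
    abs(r) < 0.3
  }, TRUE)
  expect_gte(mean(small), 0.95)
})

test_that("the 27-index battery runs, flags expected signs, stratifies", {
  coh <- generate_cohort(default_config(), n_cases = 74, seed = 42)
  m <- match_controls(coh[coh$group == "case", ],
                      coh[coh$group == "control", ])
  b <- run_comparison_battery(m)
  expect_equal(nrow(b), 27)
  expect_equal(sort(b$index), sort(panel_index_names()))
  expect_identical(attr(b, "threshold") * 27, 0.05)
  expect_identical(b$significant, b$p < attr(b, "threshold"))

  # limb/gynoid fat indices higher in cases, trunk/android lower
  row <- function(nm) b[b$index == nm, ]
  for (nm in c("fm_share_legs", "fm_share_legs_arms", "fm_share_gynoid")) {
    expect_gt(row(nm)$mean_case, row(nm)$mean_control)
    expect_true(row(nm)$significant)
  }
  for (nm in c("fm_share_trunk", "fm_share_android", "trunk_legs_fm_ratio")) {
    expect_lt(row(nm)$mean_case, row(nm)$mean_control)
    expect_true(row(nm)$significant)
  }

  strat <- run_comparison_battery(m, stratify = "bmi_class")
  expect_true(all(vapply(strat, nrow, 0L) == 27))
  by_stage <- run_comparison_battery(m, stratify = "stage")
  expect_equal(nrow(by_stage), 27)
  expect_true(all(by_stage$test[!startsWith(by_stage$test, "error")] %in%
                    c("anova", "kruskal_wallis")))

  corr <- run_correlation_battery(m)
  expect_equal(nrow(corr), 14)
  expect_true(all(corr$r >= -1 & corr$r <= 1))
})

test_that("per-index type-I error under the null respects the threshold", {
  # null simulation: both groups Gaussian; rejection rate at alpha/27 must
  # not exceed the threshold beyond Monte-Carlo error
  set.seed(48)
  thr <- bonferroni_threshold(0.05, 27)
  n_rep <- 3000
  rej <- vapply(seq_len(n_rep), function(i) {
    compare_two_groups(rnorm(40), rnorm(40), n_tests = 27)$p < thr
  }, TRUE)
  rate <- mean(rej)
  expect_lte(rate, thr + 3 * sqrt(thr * (1 - thr) / n_rep))
})
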