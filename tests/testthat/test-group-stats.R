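# Two-group statistics: summaries, t-tests (raw and from summaries),
# Mann-Whitney U with exact small-sample p-values, cohort comparison.

test_that("group summaries use the sample (n-1) standard deviation", {
  s <- summarize_group(c(1, 2, 3), "g")
  expect_equal(s$mean, 2)
  expect_equal(s$sd, 1)
  expect_equal(summarize_group(rep(4.2, 5))$sd, 0)
  expect_error(summarize_group(1), class = "strokevol_validation_error")
  # two-pass oracle on random values
  withr::with_seed(5, x <- rnorm(8, 10, 3))
  s <- summarize_group(x)
  expect_equal(s$mean, sum(x) / 8, tolerance = 1e-12)
  expect_equal(s$sd, sqrt(sum((x - sum(x) / 8)^2) / 7), tolerance = 1e-12)
})

test_that("summary t-test matches stats::t.test on raw data for both variants", {
  withr::with_seed(13, {
    x <- rnorm(8, 20, 5)
    y <- rnorm(8, 14, 3)
  })
  for (variant in c("pooled", "welch")) {
    mine <- t_test_groups(x, y, variant)
    ref <- stats::t.test(x, y, var.equal = variant == "pooled")
    expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(mine$df, unname(ref$parameter), tolerance = 1e-12)
    expect_equal(mine$p_two_sided, ref$p.value, tolerance = 1e-12)
  }
  # composition: raw-data test == summary test of the two summaries
  s1 <- summarize_group(x)
  s2 <- summarize_group(y)
  expect_identical(t_test_groups(x, y, "pooled"),
                   t_test_from_summary(s1$mean, s1$sd, s1$n,
                                       s2$mean, s2$sd, s2$n, "pooled"))
})

test_that("summary t-test p equals numerical integration of the t density", {
  res <- t_test_from_summary(27.1, 11.1, 8, 14.3, 7.2, 8, "pooled")
  quad <- 2 * stats::integrate(function(x) stats::dt(x, df = res$df),
                               abs(res$statistic), Inf,
                               rel.tol = 1e-10)$value
  expect_equal(res$p_two_sided, quad, tolerance = 1e-8)
})

test_that("t-test degenerate and invariance properties hold", {
  same <- t_test_from_summary(5, 2, 8, 5, 2, 8)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_two_sided, 1)
  expect_equal(t_test_from_summary(3, 0, 5, 3, 0, 5)$p_two_sided, 1)
  expect_warning(zero <- t_test_from_summary(3, 0, 5, 4, 0, 5))
  expect_equal(zero$p_two_sided, 0)
  expect_identical(t_test_groups(c(1, 1, 2), c(1, 1, 2))$p_two_sided, 1)

  withr::with_seed(17, {
    x <- rnorm(8, 10, 2)
    y <- rnorm(8, 12, 2)
  })
  base <- t_test_groups(x, y)
  # invariant under common shift and positive rescaling
  shifted <- t_test_groups(3.7 * x + 11, 3.7 * y + 11)
  expect_equal(shifted$statistic, base$statistic, tolerance = 1e-12)
  expect_equal(shifted$p_two_sided, base$p_two_sided, tolerance = 1e-12)
  # moving the groups further apart increases |t|
  expect_gt(abs(t_test_groups(x - 5, y)$statistic), abs(base$statistic))
  # pooled == welch when sd1 == sd2 and n1 == n2
  xa <- c(1, 2, 3, 4)
  yb <- c(10, 11, 12, 13)  # same spread, same n
  expect_equal(t_test_groups(xa, yb, "pooled")$p_two_sided,
               t_test_groups(xa, yb, "welch")$p_two_sided, tolerance = 1e-12)
})

test_that("Mann-Whitney U exact p matches the textbook example and wilcox.test", {
  res <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(res$statistic, 0)
  expect_equal(res$p_two_sided, 2 / 6)
  expect_equal(res$method, "exact")
  # symmetric inputs -> p = 1
  expect_equal(mann_whitney_u(c(1, 4), c(2, 3))$p_two_sided, 1)

  withr::with_seed(29, {
    for (i in 1:10) {
      x <- rnorm(sample(3:6, 1))
      y <- rnorm(sample(3:6, 1))
      mine <- mann_whitney_u(x, y)
      ref <- stats::wilcox.test(x, y, exact = TRUE)
      expect_equal(mine$statistic, unname(ref$statistic))
      expect_equal(mine$p_two_sided, ref$p.value, tolerance = 1e-12)
    }
  })
})

test_that("Mann-Whitney normal approximation is close to exact enumeration", {
  withr::with_seed(31, {
    for (i in 1:5) {
      x <- rnorm(8)
      y <- rnorm(8, 0.8)
      approx_p <- mann_whitney_u(x, y, exact_max = 0L)$p_two_sided
      exact_p <- mann_whitney_enum_p(x, y)
      expect_lt(abs(approx_p - exact_p), 0.02)
    }
  })
  # ties force the tie-corrected approximation
  tied <- mann_whitney_u(c(1, 2, 2, 3), c(2, 3, 3, 4))
  expect_equal(tied$method, "normal_approx")
  expect_true(tied$p_two_sided >= 0 && tied$p_two_sided <= 1)
})

test_that("compare_cohort runs the test plan per endpoint", {
  withr::with_seed(37, {
    data <- tibble::tibble(
      group = rep(c("control", "treatment"), each = 8),
      a = c(rnorm(8, 10, 2), rnorm(8, 16, 2)),
      b = rnorm(16))
  })
  res <- compare_cohort(data, c("a", "b"))
  expect_equal(nrow(res), 6)
  expect_true(all(res$significant[res$endpoint == "a" & res$test != "mann_whitney"]))
  # passthrough equals the direct call
  direct <- t_test_groups(data$a[data$group == "control"],
                          data$a[data$group == "treatment"], "pooled")
  expect_equal(res$p_two_sided[res$endpoint == "a" & res$test == "t_pooled"],
               direct$p_two_sided)
  # identical groups -> p = 1 everywhere
  same <- dplyr::mutate(data, a = rep(1:8, 2), b = rep(2:9, 2))
  res_same <- compare_cohort(same, c("a", "b"))
  expect_true(all(res_same$p_two_sided == 1))
  expect_error(compare_cohort(data, "missing_endpoint"),
               class = "strokevol_validation_error")
})
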