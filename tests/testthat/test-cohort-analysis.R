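fixture <- load_table2_fixture()

test_that("the diagnostics table composes the per-case pipeline", {
  records <- make_synthetic_cohort("mixed", 2, seed = 77)
  diag <- build_diagnostics_table(records)
  expect_equal(nrow(diag), 4)  # cases x vessels present
  expect_equal(names(diag), icpdx:::DIAGNOSTICS_COLUMNS)
  expect_true(all(diag$di_icp > 0 & diag$di_icp <= 100))
  expect_true(all(diag$ks > 0 & diag$ks < 1))
  expect_true(all(diag$ads > -1e-9))
  expect_true(all(diag$sent >= 0))
  expect_true(all(diag$diff_icp_md >= 0))
  expect_true(all(diag$kurtosis >= 1 + diag$skew^2))
  expect_false(any(duplicated(diag[c("case_id", "vessel")])))

  naked <- list(case_record("x", "arterial", 1:5))
  expect_error(build_diagnostics_table(naked), class = "icpdx_join_error")
})

test_that("cautionary synthetic cases are labelled uniform on the arterial row", {
  hits <- vapply(1:20, function(s) {
    diag <- build_diagnostics_table(make_synthetic_cohort("cautionary", 1, seed = s))
    diag$dist_type[diag$vessel == "arterial"] == "uniform"
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("group mean/se summaries reproduce the reference aggregates", {
  art_hold <- c(13.95, 16.69, 15.19, 10.08, 14.72, 17.63, 10.7)
  g <- group_summary_mean_se(art_hold, rep("hold_out", 7))
  expect_equal(round(g$mean, 2), 14.14)
  expect_equal(round(g$se, 2), 1.07)

  g2 <- group_summary_mean_se(c(3.27, 4.39), c("c", "c"))
  expect_equal(round(g2$mean, 2), 3.83)
  expect_equal(round(g2$se, 2), 0.56)
  expect_equal(round(g2$sd, 3), 0.792)

  g3 <- group_summary_mean_se(c(5, 5, 5), rep("k", 3))
  expect_equal(g3$se, 0)
})

test_that("group median/IQR summaries reproduce the reference medians", {
  ho <- fixture[fixture$subset == "hold_out", ]
  ca <- fixture[fixture$subset == "cautionary", ]
  m <- group_summary_median_iqr(fixture$sd, fixture$subset)
  expect_equal(round(m$median[m$group_label == "hold_out"], 3), 7.852)
  expect_equal(round(m$median[m$group_label == "cautionary"], 3), 11.843)
  expect_equal(round(median(ho$kurtosis), 3), 4.845)
  expect_equal(round(median(ca$skew), 4), -0.045)
  expect_equal(group_summary_median_iqr(c(1, 2, 3), rep("g", 3))$median, 2)
})

test_that("univariate F tests reproduce the cohort association table", {
  f_lat <- univariate_f(fixture$diff_icp_md, fixture$laterality, "categorical")
  expect_equal(f_lat$f_value, 8.5062, tolerance = 1e-4)
  expect_equal(f_lat$p_value, 0.01009, tolerance = 1e-3)
  expect_equal(c(f_lat$df1, f_lat$df2), c(1, 16))

  f_case <- univariate_f(fixture$diff_icp_md, fixture$subset, "categorical")
  expect_equal(f_case$f_value, 65.217, tolerance = 1e-4)

  f_iop <- univariate_f(fixture$diff_icp_md, fixture$n_iop_levels, "continuous")
  expect_equal(f_iop$f_value, 5.1643, tolerance = 1e-4)

  same_mean <- univariate_f(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3),
                            "categorical")
  expect_equal(same_mean$f_value, 0)

  expect_error(univariate_f(c(1, 2, 3), c("a", "a", "a"), "categorical"),
               class = "icpdx_degenerate_error")
  expect_error(univariate_f(c(2, 2, 2), c(1, 2, 3), "continuous"),
               class = "icpdx_degenerate_error")
})

test_that("a two-level F equals the squared pooled t statistic", {
  withr::local_seed(61)
  y <- rnorm(14); x <- rep(c("a", "b"), 7)
  f <- univariate_f(y, x, "categorical")
  t2 <- t.test(y ~ x, var.equal = TRUE)$statistic^2
  expect_equal(f$f_value, unname(t2), tolerance = 1e-10)
})

test_that("Pearson correlations reproduce the reference relationships", {
  r_pool <- pearson_r(fixture$di_icp, fixture$diff_icp_md)
  expect_equal(r_pool$r, -0.5213, tolerance = 2e-4)
  expect_equal(r_pool$se_textbook, sqrt((1 - r_pool$r^2) / 16))

  r_sent <- pearson_r(fixture$sent, fixture$diff_icp_md)
  expect_equal(r_sent$r, 0.4832, tolerance = 2e-4)

  art <- fixture[fixture$vessel == "arterial", ]
  ven <- fixture[fixture$vessel == "venous", ]
  expect_equal(round(pearson_r(art$di_icp, art$diff_icp_md)$r, 2), -0.76)
  expect_equal(round(pearson_r(ven$di_icp, ven$diff_icp_md)$r, 2), -0.10)

  expect_equal(pearson_r(1:10, 1:10)$r, 1)
  x <- withr::with_seed(62, rnorm(30)); y <- withr::with_seed(63, rnorm(30))
  expect_equal(pearson_r(2 * x + 1, y)$r, pearson_r(x, y)$r, tolerance = 1e-12)
  expect_error(pearson_r(rep(1, 5), 1:5), class = "icpdx_degenerate_error")
})

test_that("the correlation matrix codes discrete variables and is symmetric", {
  cm <- correlation_matrix(fixture, c("diff_icp_md", "laterality", "di_icp", "sent"))
  expect_equal(unname(diag(cm$r)), rep(1, 4))
  expect_equal(cm$r, t(cm$r))
  expect_equal(cm$r["laterality", "diff_icp_md"], -0.59, tolerance = 5e-3)
  expect_equal(cm$r["di_icp", "diff_icp_md"], -0.5213, tolerance = 2e-4)
  expect_error(correlation_matrix(fixture, c("diff_icp_md", "nope")),
               class = "icpdx_name_error")
})

test_that("internal consistency: r^2 equals F/(F + n - 2) for a binary predictor", {
  r <- pearson_r(code_variable(fixture, "laterality"), fixture$diff_icp_md)$r
  f <- univariate_f(fixture$diff_icp_md, fixture$laterality, "categorical")$f_value
  expect_equal(r^2, f / (f + 16), tolerance = 1e-12)
})

test_that("polychoric correlation behaves at independence and the boundary", {
  indep <- matrix(c(25, 25, 25, 25), 2)
  expect_lt(abs(polychoric_rho(indep)$rho), 1e-3)

  conc <- polychoric_rho(matrix(c(50, 0, 0, 50), 2))
  expect_gte(conc$rho, 0.99)
  expect_true(conc$boundary)

  expect_error(polychoric_rho(matrix(c(5, 5, 0, 0), 2)),
               class = "icpdx_validation_error")
  expect_error(polychoric_rho(matrix(1:3, 1)), class = "icpdx_validation_error")
})

test_that("polychoric correlation recovers a generating latent rho", {
  set.seed(64)
  z1 <- rnorm(1e4); z2 <- 0.5 * z1 + sqrt(1 - 0.25) * rnorm(1e4)
  tab <- base::table(z1 > median(z1), z2 > median(z2))
  expect_lt(abs(polychoric_rho(tab)$rho - 0.5), 0.05)
})

test_that("rank-sum tests enumerate exactly for small samples", {
  w <- wilcoxon_ranksum(c(1, 2, 3), c(4, 5, 6))
  expect_equal(w$statistic, 0)
  expect_equal(w$p_raw, 0.1)   # 2/20 assignments as extreme, two-sided

  w_same <- wilcoxon_ranksum(c(1, 2, 3, 4.5), c(1, 2, 3, 4.5))
  expect_gt(w_same$p_raw, 0.95)

  w_bonf <- wilcoxon_ranksum(c(1, 2, 3), c(4, 5, 6), m_tests = 10)
  expect_equal(w_bonf$p_bonferroni, min(1, 10 * w_bonf$p_raw))
  expect_error(wilcoxon_ranksum(1:3, 4:6, m_tests = 0),
               class = "icpdx_argument_error")
})

test_that("exact and approximate rank-sum p-values agree for n1 = n2 = 6", {
  withr::local_seed(65)
  for (i in 1:10) {
    g1 <- rnorm(6); g2 <- rnorm(6, 0.5)
    p_exact <- wilcoxon_ranksum(g1, g2)$p_raw  # 12 <= 12: exact path
    p_approx <- suppressWarnings(
      stats::wilcox.test(g1, g2, exact = FALSE, correct = TRUE)$p.value)
    expect_lt(abs(p_exact - p_approx), 0.03)
  }
})

test_that("harmonic descriptives match the moment oracle per group", {
  h <- tibble::tibble(vessel = "artery", group = "hold_out",
                      hrw_a = c(1, 2, 3, 4, 10))
  d <- describe_harmonics(h, "hrw_a")
  expect_equal(d$median, 3)
  expect_equal(d$iqr, 2)
  expect_equal(d$skew, 36 / 10^1.5, tolerance = 1e-10)

  const <- tibble::tibble(vessel = "vein", group = "hold_out", a_n1 = rep(2, 5))
  dc <- describe_harmonics(const, "a_n1")
  expect_equal(dc$iqr, 0)
  expect_equal(dc$range, 0)
  expect_error(describe_harmonics(h, "missing_field"), class = "icpdx_name_error")
})

test_that("the 2-sd outlier rule flags the cautionary venous DI values", {
  ven_hold <- fixture$di_icp[fixture$vessel == "venous" &
                               fixture$subset == "hold_out"]
  expect_equal(flag_two_sd_outliers(c(24.46, 8.22), ven_hold), c(TRUE, TRUE))
  expect_false(flag_two_sd_outliers(mean(ven_hold), ven_hold))
  expect_warning(f0 <- flag_two_sd_outliers(c(1, 99), c(5, 5, 5)), "zero")
  expect_equal(f0, c(FALSE, FALSE))
  expect_error(flag_two_sd_outliers(1, 5), class = "icpdx_validation_error")
})
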