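test_that("one-way ANOVA matches the hand-computed decomposition", {
  a <- one_way_anova(list(g1 = c(1, 2, 3), g2 = c(2, 3, 4)))
  expect_equal(a$ss_between, 1.5)
  expect_equal(a$ss_within, 4.0)
  expect_equal(a$f_ratio, 1.5)
  expect_equal(a$df_between, 1L)
  expect_equal(a$df_within, 4L)

  same <- one_way_anova(list(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(same$ss_between, 0)
  expect_equal(same$f_ratio, 0)

  expect_error(one_way_anova(list(c(1, 2), c(3))),
               class = "phagemech_bad_groups")
})

test_that("ANOVA agrees with the built-in aov cross-check", {
  for (seed in 1:3) {
    d <- withr::with_seed(seed, data.frame(
      value = stats::rnorm(60),
      group = rep(c("a", "b", "c"), each = 20)
    ))
    mine <- one_way_anova(d)
    ref <- summary(stats::aov(value ~ group, data = d))[[1]]
    expect_equal(mine$ss_between, ref["group", "Sum Sq"], tolerance = 1e-9)
    expect_equal(mine$ss_within, ref["Residuals", "Sum Sq"],
                 tolerance = 1e-9)
    expect_equal(mine$f_ratio, ref["group", "F value"], tolerance = 1e-9)
    expect_equal(mine$p_value, ref["group", "Pr(>F)"], tolerance = 1e-9)
  }
})

test_that("two-group ANOVA F equals the squared pooled-variance t", {
  x <- withr::with_seed(5, stats::rnorm(25, 0))
  y <- withr::with_seed(6, stats::rnorm(30, 0.4))
  a <- one_way_anova(list(x, y))
  t2 <- stats::t.test(x, y, var.equal = TRUE)$statistic^2
  expect_equal(a$f_ratio, unname(t2), tolerance = 1e-9)
})

test_that("sum-of-squares identity and tidy table structure hold", {
  a <- one_way_anova(list(withr::with_seed(1, stats::rnorm(15)),
                          withr::with_seed(2, stats::rnorm(20, 1))))
  expect_equal(a$ss_total, a$ss_between + a$ss_within, tolerance = 1e-9)
  expect_equal(a$df_total, a$df_between + a$df_within)
  # table-from-sums path agrees with the raw-data path to 1e-9 relative
  b <- anova_from_sums(a$ss_between, a$df_between, a$ss_within, a$df_within)
  expect_equal(b$f_ratio, a$f_ratio, tolerance = 1e-9)
  expect_equal(b$p_value, a$p_value, tolerance = 1e-9)
  tt <- tidy(a)
  expect_equal(tt$source, c("Between Groups", "Within Groups", "Total"))
  expect_equal(tt$ms[1:2], c(a$ms_between, a$ms_within))
})

test_that("anova_from_sums reconstructs the printed two-genome table", {
  a <- anova_from_sums(17.288, 1, 1823.138, 45197, alpha = 0.05)
  expect_equal(a$f_ratio, 428.585, tolerance = 0.01 / 428.585)
  expect_equal(a$ms_within, 0.040, tolerance = 0.01)
  expect_equal(a$f_critical, 3.842, tolerance = 0.001 / 3.842)
  expect_lt(a$p_value, 1e-90)

  degenerate <- anova_from_sums(0, 1, 10, 10)
  expect_equal(degenerate$f_ratio, 0)
  expect_equal(degenerate$p_value, 1)
})

test_that("f_critical behaves like the F distribution", {
  expect_equal(f_critical(1, 45197, 0.05), 3.842, tolerance = 0.001 / 3.842)
  expect_equal(f_critical(1, 1e7, 0.05), stats::qchisq(0.95, 1),
               tolerance = 1e-4)
  expect_gt(f_critical(1, 10, 0.05), f_critical(1, 100, 0.05))
  expect_error(f_critical(1, 10, 1.5), class = "phagemech_bad_alpha")
})

test_that("Mann-Whitney U and exact p match full enumeration", {
  r <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$u_statistic, 0)
  expect_equal(r$u_prime, 9)
  expect_equal(r$p_value, 0.1)
  expect_equal(r$method, "exact")

  for (seed in 1:4) {
    ab <- withr::with_seed(seed, list(a = stats::rnorm(5),
                                      b = stats::rnorm(7, 0.5)))
    mine <- mann_whitney_u(ab$a, ab$b)
    expect_equal(mine$method, "exact")
    expect_equal(mine$p_value, brute_force_mwu_p(ab$a, ab$b))
    expect_equal(mine$u_statistic + mine$u_prime, 35)
  }
})

test_that("Mann-Whitney handles ties and degenerate samples", {
  const <- mann_whitney_u(rep(1, 6), rep(1, 8))
  expect_equal(const$u_statistic, 24)  # n1 * n2 / 2
  expect_equal(const$p_value, 1)
  expect_true(const$method == "normal-approximation")
  expect_error(mann_whitney_u(numeric(0), 1),
               class = "phagemech_empty_sample")
  expect_error(mann_whitney_u(c(1, 1, 2), c(2, 3), mode = "exact"),
               class = "phagemech_exact_ties")
})

test_that("normal approximation tracks the exact p at moderate n", {
  for (seed in 1:3) {
    ab <- withr::with_seed(seed + 50, list(a = stats::rnorm(15),
                                           b = stats::rnorm(15, 0.5)))
    ex <- mann_whitney_u(ab$a, ab$b, mode = "exact")
    ap <- mann_whitney_u(ab$a, ab$b, mode = "approx")
    expect_lt(abs(ap$p_value - ex$p_value) / ex$p_value, 0.10)
  }
})

test_that("Mann-Whitney is label-swap symmetric", {
  a <- withr::with_seed(9, stats::rnorm(12))
  b <- withr::with_seed(10, stats::rnorm(9, 0.3))
  r1 <- mann_whitney_u(a, b)
  r2 <- mann_whitney_u(b, a)
  expect_equal(r1$p_value, r2$p_value)
  expect_equal(r1$u_statistic, r2$u_prime)
})

test_that("Mann-Whitney holds its nominal type-I error rate", {
  rejections <- withr::with_seed(123, {
    mean(vapply(1:1000, function(i) {
      mann_whitney_u(stats::rnorm(30), stats::rnorm(30),
                     mode = "approx")$p_value < 0.05
    }, logical(1)))
  })
  expect_gt(rejections, 0.03)
  expect_lt(rejections, 0.07)
})

test_that("boxplot statistics follow interpolated quartiles and Tukey fences", {
  b <- boxplot_stats(1:8)
  expect_equal(b$median, 4.5)
  expect_equal(b$q1, 2.75)
  expect_equal(b$q3, 6.25)
  expect_length(b$outliers, 0)
  expect_equal(b$whisker_low, 1)
  expect_equal(b$whisker_high, 8)

  const <- boxplot_stats(rep(2, 10))
  expect_equal(const$iqr, 0)
  expect_equal(const$whisker_low, const$whisker_high)

  out <- boxplot_stats(c(1:8, 100))
  expect_equal(out$outliers, 100)
  expect_error(boxplot_stats(c(1, 2, 3)), class = "phagemech_too_short")
})
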