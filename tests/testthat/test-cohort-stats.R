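test_that("hyperglycemia designation needs consecutive readings > 250", {
  expect_false(designate_hyperglycemic(c(180, 190, 200)))
  expect_true(designate_hyperglycemic(c(240, 260, 270)))
  expect_false(designate_hyperglycemic(c(300, 200, 300, 200)))
  expect_false(designate_hyperglycemic(c(250, 250, 250)))  # strict >
  expect_error(designate_hyperglycemic(300), "2 weekly")
})

test_that("stall rate is exact with the printed display convention", {
  r1 <- stall_rate(9, n = 589)
  expect_equal(as.numeric(r1), 100 * 9 / 589)
  expect_identical(attr(r1, "display"), "1.52%")
  r2 <- stall_rate(7, n = 440)
  expect_identical(attr(r2, "display"), "1.59%")
  expect_equal(as.numeric(stall_rate(rep(FALSE, 50))), 0)
  expect_error(stall_rate(logical()), "no segments")
  # count recovered exactly before any rounding
  for (k in c(0, 3, 9)) {
    expect_equal(as.numeric(stall_rate(k, n = 589)) * 589 / 100, k)
  }
  # flag-vector and count forms agree
  flags <- c(rep(TRUE, 9), rep(FALSE, 580))
  expect_equal(as.numeric(stall_rate(flags)),
               as.numeric(stall_rate(9, n = 589)))
})

test_that("exact two-sided tolerance factors match published values", {
  # exact values from the standard normal tolerance tables (95%/95%)
  expect_equal(tolerance_factor_normal(10), 3.3935, tolerance = 1e-3)
  expect_equal(tolerance_factor_normal(50), 2.3828, tolerance = 1e-3)
  # Howe approximation tracks the exact factor to well under 1%
  for (n in c(10, 38, 100)) {
    expect_lt(abs(tolerance_factor_normal(n, method = "howe") /
                    tolerance_factor_normal(n) - 1), 0.01)
  }
  # k shrinks with n and always exceeds the infinite-n normal quantile
  ks <- vapply(c(5, 15, 60), tolerance_factor_normal, 1)
  expect_true(all(diff(ks) < 0))
  expect_true(all(ks > stats::qnorm(0.975)))
})

test_that("Bland-Altman against the grader mean behaves algebraically", {
  withr::with_seed(30, {
    base <- stats::rnorm(38, 100, 40)
  })
  # all graders identical: zero bias, zero-width limits, degenerate flag
  same <- cbind(g1 = base, g2 = base, g3 = base)
  ba <- bland_altman(same)
  expect_equal(ba$bias, rep(0, 3))
  expect_equal(ba$loa_low, rep(0, 3))
  expect_equal(ba$loa_high, rep(0, 3))
  expect_true(all(ba$degenerate))

  # one grader offset by c: its bias is c * (1 - 1/n_graders)
  off <- cbind(g1 = base + 6, g2 = base, g3 = base, g4 = base)
  ba2 <- bland_altman(off)
  expect_equal(ba2$bias[1], 6 * (1 - 1 / 4))
  expect_equal(ba2$bias[-1], rep(-6 / 4, 3))
  # biases sum to zero exactly: the reference is the grader mean
  expect_lt(abs(sum(ba2$bias)), 1e-10)
  # CIs contain their point estimates
  expect_true(all(ba2$ci_bias_low <= ba2$bias & ba2$bias <=
                    ba2$ci_bias_high))
  expect_true(all(ba2$ci_loa_high_lo <= ba2$loa_high &
                    ba2$loa_high <= ba2$ci_loa_high_hi))

  expect_error(bland_altman(cbind(base)), "2 graders")
  expect_error(bland_altman(matrix(1:4, 2, 2)), "3 capillaries")
})

test_that("Monte-Carlo grader noise recovers the limits of agreement", {
  # 5 graders x 38 capillaries, per-grader noise SD 5 cells/s; the
  # difference to the grader mean has SD 5*sqrt(1 - 1/5)
  sd_d_true <- 5 * sqrt(1 - 1 / 5)
  half <- vapply(1:100, function(s) {
    withr::with_seed(1000 + s, {
      truth <- stats::rnorm(38, 100, 40)
      counts <- truth + matrix(stats::rnorm(38 * 5, 0, 5), 38, 5)
    })
    ba <- bland_altman(counts, tol_method = "howe")
    mean((ba$loa_high - ba$loa_low) / 2)
  }, 1)
  expect_lt(abs(mean(half) - 1.96 * sd_d_true) / (1.96 * sd_d_true),
            0.15)
})

test_that("adjusted skew and excess kurtosis match their formulas", {
  expect_equal(adjusted_skew(c(-1, 0, 1)), 0)
  # independent brute-force evaluation for {0, 0, 1}: sqrt(3)
  expect_equal(adjusted_skew(c(0, 0, 1)), sqrt(3), tolerance = 1e-12)
  x <- c(2, 4, 4, 7, 12)
  n <- 5; s <- stats::sd(x); m3 <- mean((x - mean(x))^3)
  expect_equal(adjusted_skew(x), n^2 / ((n - 1) * (n - 2)) * m3 / s^3)
  withr::with_seed(77, g <- stats::rnorm(1e4))
  expect_lt(abs(adjusted_skew(g)), 0.05)
  expect_lt(abs(excess_kurtosis(g)), 0.1)
  expect_error(adjusted_skew(c(1, 1, 1)), "zero variance")
  expect_error(adjusted_skew(c(1, 2)), "n >= 3")
  expect_error(excess_kurtosis(c(1, 2, 3)), "n >= 4")
})

test_that("Student's t comparison handles identity and separation", {
  a <- c(10, 12, 14, 16)
  cmp <- group_compare(a, a)
  expect_equal(cmp$p, 1)
  expect_equal(cmp$t, 0)
  # degenerate equal-mean case
  expect_equal(group_compare(c(5, 5), c(5, 5))$p, 1)
  expect_error(group_compare(c(5, 5), c(6, 6)), "unbounded")
  # clear separation
  withr::with_seed(9, {
    x <- stats::rnorm(20, 0, 1); y <- stats::rnorm(20, 50, 1)
  })
  expect_lt(group_compare(x, y)$p, 1e-6)
  # |t| symmetric in group order
  expect_equal(abs(group_compare(x, y)$t), abs(group_compare(y, x)$t))
  # pooled-variance default matches the classical Student statistic
  expect_equal(group_compare(x, y)$t,
               unname(stats::t.test(x, y, var.equal = TRUE)$statistic))
})

test_that("regression summary returns OLS slope and Pearson R^2", {
  x <- 1:20
  r <- regression_r2_slope(x, 2 * x)
  expect_equal(r$slope, 2)
  expect_equal(r$r_squared, 1)
  withr::with_seed(21, {
    xn <- stats::rnorm(1e4); yn <- stats::rnorm(1e4)
  })
  expect_lt(regression_r2_slope(xn, yn)$r_squared, 0.01)
  expect_error(regression_r2_slope(rep(1, 5), 1:5), "var\\(x\\)")
  expect_error(regression_r2_slope(1:2, 1:2), "n >= 3")
})

test_that("built-in flux-diameter association is recovered by OLS", {
  sl <- vapply(1:20, function(s) {
    co <- simulate_cohort(cohort_sim_params(seed = 900 + s))
    caps <- co$capillaries[!co$capillaries$stalled &
                             co$capillaries$group == "euglycemic", ]
    regression_r2_slope(caps$diameter_um, caps$flux_cells_s)$slope
  }, 1)
  # generator builds in 45 cells/s per um of lumen; weak association
  # (R^2 ~ 0.1) makes single-seed slopes noisy, the average is not
  expect_lt(abs(mean(sl) - 45) / 45, 0.2)
})

test_that("age grouping splits young and mature adults at week 13", {
  expect_identical(age_group(12), "young")
  expect_identical(age_group(13), "mature")
  expect_identical(age_group(5), "young")
  expect_error(age_group(4), "epoch")
  expect_identical(age_group(c(5, 12, 13, 18)),
                   c("young", "young", "mature", "mature"))
})

test_that("weekly summaries aggregate by group and week", {
  co <- simulate_cohort(cohort_sim_params(seed = 17,
                                          n_mice_per_group = 3))
  ws <- weekly_summary(co, "glucose_mgdl")
  expect_identical(sort(unique(ws$week)), sort(unique(co$mice$week)))
  expect_true(all(ws$n == 3))
  # single observation cells report SD 0
  one <- co
  one$mice <- co$mice[!duplicated(paste(co$mice$group, co$mice$week)), ]
  expect_true(all(weekly_summary(one, "glucose_mgdl")$sd == 0))
  expect_error(weekly_summary(co, "not_a_variable"), "unknown")
  # invariant to row order
  shuf <- co
  withr::with_seed(4, shuf$mice <- co$mice[sample(nrow(co$mice)), ])
  expect_equal(weekly_summary(shuf, "glucose_mgdl"), ws)
})
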