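test_that("evaluate_model matches the closed form and its limits", {
  p <- lc_params(0.65, 7.28, 14.17)
  # value at trial 1 is exactly B3
  expect_identical(evaluate_model(p, 1), 7.28)
  # direct evaluation at x = 3: B4 - (B4 - B3) * exp(-2 * B2)
  expect_equal(evaluate_model(p, 3), 14.17 - 6.89 * exp(-1.3),
               tolerance = 1e-12)
  # flat curve when B3 = B4
  expect_equal(evaluate_model(lc_params(1.3, 9, 9), c(1, 2, 7)),
               rep(9, 3))
  # monotone increasing when B4 > B3, decreasing when B4 < B3,
  # limit at large x equals B4
  for (i in 1:20) {
    set.seed(i)
    b2 <- runif(1, 0.1, 2)
    b3 <- runif(1, 0, 10)
    b4 <- runif(1, 0, 16)
    y <- evaluate_model(c(B2 = b2, B3 = b3, B4 = b4), 1:8)
    if (b4 > b3) expect_true(all(diff(y) > 0))
    if (b4 < b3) expect_true(all(diff(y) < 0))
    expect_equal(evaluate_model(c(B2 = b2, B3 = b3, B4 = b4), 1e6), b4,
                 tolerance = 1e-9)
  }
  # parameter domain errors
  expect_error(evaluate_model(c(B2 = -1, B3 = 5, B4 = 10), 2), "B2")
  expect_error(evaluate_model(p, 0.5), "trial numbers")
})

test_that("fitting recovers noiseless generating parameters exactly", {
  for (i in 1:10) {
    set.seed(100 + i)
    truth <- c(B2 = runif(1, 0.2, 2), B3 = runif(1, 1, 8),
               B4 = runif(1, 9, 16))
    y <- evaluate_model(truth, 1:5)
    f <- fit_learning_curve(y)
    expect_true(f$converged)
    expect_equal(unname(f$params), unname(truth), tolerance = 1e-6)
    expect_equal(f$r_squared, 1, tolerance = 1e-9)
    expect_equal(unname(f$se), rep(0, 3), tolerance = 1e-6)
  }
  # the documented three-point exact-interpolation case
  y3 <- evaluate_model(c(B2 = 0.7, B3 = 6, B4 = 14), 1:3)
  f3 <- fit_learning_curve(y3)
  expect_equal(unname(f3$params), c(0.7, 6, 14), tolerance = 1e-5)
})

test_that("fit is invariant to admissible initialisations on
           well-conditioned data", {
  set.seed(7)
  y <- evaluate_model(c(B2 = 0.8, B3 = 5, B4 = 13), 1:5) +
    rnorm(5, 0, 0.3)
  y <- pmin(pmax(y, 0), 16)
  base <- fit_learning_curve(y)
  for (init in list(c(B2 = 0.2, B3 = 2, B4 = 15),
                    c(B2 = 1.5, B3 = 8, B4 = 10),
                    c(B2 = 0.5, B3 = 5, B4 = 13))) {
    f <- fit_learning_curve(y, init = init)
    expect_equal(unname(f$params), unname(base$params), tolerance = 1e-8)
  }
})

test_that("asymptotic SEs match a finite-difference Jacobian oracle", {
  set.seed(11)
  y <- evaluate_model(c(B2 = 0.6, B3 = 6, B4 = 13), 1:5) + rnorm(5, 0, 1)
  y <- pmin(pmax(y, 0), 16)
  f <- fit_learning_curve(y)
  se_fd <- fd_asymptotic_se(f$params, 1:5, f$ss_res)
  expect_equal(unname(f$se), se_fd, tolerance = 1e-4)
})

test_that("model R-squared beats the straight line on model data", {
  set.seed(3)
  for (i in 1:5) {
    truth <- c(B2 = runif(1, 0.4, 1.5), B3 = runif(1, 2, 7),
               B4 = runif(1, 10, 16))
    y <- evaluate_model(truth, 1:5)
    f <- fit_learning_curve(y)
    sl <- learning_slope(y)
    ic <- mean(y) - sl * 3
    r2_line <- 1 - sum((y - (ic + sl * (1:5)))^2) /
      sum((y - mean(y))^2)
    expect_gte(f$r_squared, r2_line)
  }
})

test_that("fit input validation and degenerate-curve flagging", {
  expect_error(fit_learning_curve(c(5, 7)), "at least 3")
  expect_error(fit_learning_curve(c(5, 7, 20)), "\\[0, 16\\]")
  expect_error(fit_learning_curve(c(5, 7, 9), trials = c(1, 1, 2)),
               "strictly increasing")
  # near-flat noisy series: B2 weakly identified, flagged not hidden
  set.seed(21)
  y <- pmin(pmax(round(10 + rnorm(5, 0, 1)), 0), 16)
  f <- fit_learning_curve(y)
  expect_true(f$converged)
  if (is.finite(f$se[["B2"]]) && f$se[["B2"]] > abs(f$params[["B2"]])) {
    expect_true(f$b2_unreliable)
  }
})

test_that("coefficient comparison is a two-sided Wald z-test", {
  y <- c(7.26, 10.67, 12.22, 13.09, 13.76)
  f <- fit_learning_curve(y)
  same <- compare_coefficients(f, f, "B3")
  expect_equal(unname(same$statistic), 0)
  expect_equal(same$p.value, 1)
  # z at the 5% two-sided quantile
  set.seed(5)
  ya <- pmin(pmax(evaluate_model(c(B2 = 0.7, B3 = 6, B4 = 13), 1:5) +
                    rnorm(5, 0, 0.5), 0), 16)
  fa <- fit_learning_curve(ya)
  fb <- fa
  fb$params[["B3"]] <- fa$params[["B3"]] +
    1.96 * sqrt(2 * fa$se[["B3"]]^2)
  cc <- compare_coefficients(fa, fb, "B3")
  expect_equal(cc$p.value, 0.05, tolerance = 1e-3)
  # healthy-male vs healthy-female averaged-curve B3 comparison:
  # (7.63 +/- 0.15) vs (5.90 +/- 0.17) is decisively significant
  fem <- fit_learning_curve(
    unlist(cvlt_trial_means[cvlt_trial_means$item == 4, paste0("t", 1:5)]))
  mal <- fit_learning_curve(
    unlist(cvlt_trial_means[cvlt_trial_means$item == 3, paste0("t", 1:5)]))
  cc2 <- compare_coefficients(fem, mal, "B3")
  expect_gt(unname(cc2$statistic), 0)
  expect_lt(cc2$p.value, 0.01)
  # plugging the published SEs directly into the Wald formula
  z_pub <- (7.63 - 5.90) / sqrt(0.15^2 + 0.17^2)
  expect_equal(z_pub, 7.63, tolerance = 0.01)
})

test_that("learning slope and max-minus-first summaries", {
  expect_equal(learning_slope(c(2, 4, 6, 8, 10)), 2)
  expect_equal(learning_slope(c(5, 5, 5, 5, 5)), 0)
  # closed-form OLS on the healthy-group mean curve: sum((x-3)*y)/10
  y <- c(7.26, 10.67, 12.22, 13.09, 13.76)
  expect_equal(learning_slope(y), sum((1:5 - 3) * y) / 10)
  expect_equal(learning_slope(y), unname(coef(lm(y ~ x,
                                                 data.frame(x = 1:5, y)))[2]))
  expect_error(learning_slope(5), "at least 2")

  expect_equal(max_minus_first(c(5, 8, 10, 9, 11)), 6)
  expect_equal(max_minus_first(c(12, 10, 9, 8, 7)), 0)
  expect_equal(max_minus_first(c(4.44, 7.44, 9.78, 10.33, 11.00)), 6.56)
})
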