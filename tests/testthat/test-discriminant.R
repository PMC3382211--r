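# Deterministic toy groups used in several blocks.
make_groups <- function(seed = 4, n = 30, gap = 4) {
  set.seed(seed)
  list(a = matrix(rnorm(2 * n, mean = c(gap, gap / 2)), ncol = 2,
                  byrow = TRUE, dimnames = list(NULL, c("u", "v"))),
       b = matrix(rnorm(2 * n, mean = c(0, 0)), ncol = 2, byrow = TRUE,
                  dimnames = list(NULL, c("u", "v"))))
}

test_that("univariate discriminant has the closed-form midpoint cutoff", {
  set.seed(2)
  a <- matrix(4 + rnorm(40), ncol = 1, dimnames = list(NULL, "B3"))
  b <- matrix(8 + rnorm(40), ncol = 1, dimnames = list(NULL, "B3"))
  m <- fit_lda(b, a)  # reference group has the larger mean
  cut <- threshold_from_function(m$coefficients[["C0"]],
                                 m$coefficients[["B3"]], m$boundary)
  # equal-n univariate: cutoff is the midpoint of the two predictor means
  expect_equal(cut, (mean(a) + mean(b)) / 2, tolerance = 1e-10)
  # weight is 1/pooled SD
  s_pool <- sqrt((sum((a - mean(a))^2) + sum((b - mean(b))^2)) / 78)
  expect_equal(m$coefficients[["B3"]], 1 / s_pool, tolerance = 1e-10)
})

test_that("discriminant scores satisfy the scaling conventions", {
  g <- make_groups()
  m <- fit_lda(g$a, g$b)
  sa <- classify(m, g$a)$score
  sb <- classify(m, g$b)$score
  # pooled within-group variance of training scores is exactly 1
  pooled <- (sum((sa - mean(sa))^2) + sum((sb - mean(sb))^2)) /
    (length(sa) + length(sb) - 2)
  expect_equal(pooled, 1, tolerance = 1e-9)
  # size-weighted grand mean score is 0
  expect_equal(mean(c(sa, sb)), 0, tolerance = 1e-9)
  # reference centroid larger; boundary strictly between centroids
  expect_gt(m$centroids[[1]], m$centroids[[2]])
  expect_true(m$boundary > m$centroids[[2]] &&
                m$boundary < m$centroids[[1]])
  # weighted convention puts the boundary at score 0
  mw <- fit_lda(g$a, g$b, boundary = "weighted")
  expect_equal(mw$boundary, 0)
})

test_that("discriminant direction matches a 1-degree projection-search
           oracle on 2-D toys", {
  for (seed in c(4, 5, 6)) {
    g <- make_groups(seed)
    m <- fit_lda(g$a, g$b)
    w <- m$coefficients[c("u", "v")]
    w <- w / sqrt(sum(w^2))
    wg <- grid_lda_direction(g$a, g$b)
    # same axis up to sign, within the 1-degree grid resolution
    cosang <- abs(sum(w * wg))
    expect_gte(cosang, cos(pi / 180))
  }
})

test_that("Wilks' lambda and Bartlett chi-square behave at the
           no-separation limit and reconcile with published pairs", {
  expect_equal(bartlett_chi2(1, 100, 5), 0)
  expect_error(bartlett_chi2(1.2, 50, 1), "lambda")
  # identical group means: lambda ~ 1 and the direction is undefined
  set.seed(8)
  x <- matrix(rnorm(60), ncol = 2)
  expect_error(fit_lda(x, x), "coincide")
  # male B4 example: -(74 - 1 - 1.5) * ln(.534) vs printed 44.820
  expect_equal(bartlett_chi2(0.534, 74, 1), 44.820, tolerance = 0.05)
  # every published (lambda, n, p) pair reproduces its printed chi2
  # within 0.5 (the slack induced by lambda's 3-decimal rounding)
  for (i in seq_len(nrow(cvlt_wilks_tests))) {
    r <- cvlt_wilks_tests[i, ]
    expect_equal(bartlett_chi2(r$wilks_lambda, r$n_a + r$n_b,
                               r$predictors),
                 r$chi2, tolerance = 0.5 / r$chi2)
  }
})

test_that("classification is boundary-inclusive and invariant to common
           positive rescaling", {
  m <- discriminant_function(-4.518, c(B3 = 0.937), 0.958)
  # a case scoring exactly at the boundary is healthy-like
  at_boundary <- (0.958 + 4.518) / 0.937
  expect_equal(as.character(classify(m, at_boundary)$label), "control")
  expect_equal(as.character(classify(m, at_boundary - 1e-9)$label),
               "patient")
  # rescaling coefficients and boundary together changes nothing
  m2 <- discriminant_function(-4.518 * 3, c(B3 = 0.937 * 3), 0.958 * 3)
  x <- seq(2, 9, by = 0.25)
  expect_equal(as.character(classify(m, x)$label),
               as.character(classify(m2, x)$label))
  m5 <- discriminant_function(-4.774, c(t1 = 0.1564, t2 = -0.040,
                                        t3 = 0.047, t4 = -0.04906,
                                        t5 = 0.349), 0.420)
  expect_error(classify(m5, c(10, 12, 13)), "expected 5 predictor")
  expect_error(threshold_from_function(1, 0, 0.5), "nonzero")
  expect_equal(threshold_from_function(0, 1, 0), 0)
})

test_that("holdout verification counts agreement against an expected
           label", {
  g <- make_groups(10, n = 25, gap = 6)
  m <- fit_lda(g$a, g$b, groups = c("control", "patient"))
  # training reference group verifies ~100% healthy-like
  vh <- verify_holdout(m, g$a, "control")
  expect_equal(vh$percent_match, 100)
  # far-below holdout is fully on the patient side
  far <- sweep(g$b, 2, c(10, 5))
  expect_equal(verify_holdout(m, far, "patient")$percent_match, 100)
  # borderline holdout: percent equals the direct count at the boundary
  straddle <- sweep(g$a, 2, c(2, 1))
  sc <- classify(m, straddle)
  vh2 <- verify_holdout(m, straddle, "control")
  expect_equal(vh2$n_match, sum(sc$score >= m$boundary))
  expect_error(verify_holdout(m, g$a, "banana"), "expected_label")
})

test_that("per-trial group comparison is the pooled-variance t-test", {
  set.seed(12)
  A <- matrix(rnorm(50, 10), ncol = 5)
  B <- matrix(rnorm(50, 8), ncol = 5)
  res <- compare_group_means(A, B)
  expect_equal(nrow(res), 5)
  # hand-computed pooled t for the first column
  a <- A[, 1]; b <- B[, 1]
  sp <- sqrt(((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
               (length(a) + length(b) - 2))
  t_hand <- (mean(a) - mean(b)) / (sp * sqrt(1 / length(a) +
                                               1 / length(b)))
  expect_equal(res$t[1], t_hand, tolerance = 1e-12)
  # antisymmetry: swapped order negates t, keeps p
  swapped <- compare_group_means(B, A)
  expect_equal(swapped$t, -res$t)
  expect_equal(swapped$p_value, res$p_value)
  # identical groups: t = 0, p = 1
  same <- compare_group_means(A, A)
  expect_equal(same$t, rep(0, 5))
  expect_equal(same$p_value, rep(1, 5))
  expect_error(compare_group_means(matrix(1, 3, 2), matrix(1, 3, 2)),
               "zero pooled variance")
})

test_that("degenerate discriminant inputs raise informative errors", {
  set.seed(13)
  a <- cbind(x = rnorm(10, 4), y = 0)
  b <- cbind(x = rnorm(10, 8), y = 0)
  a[, "y"] <- 2 * a[, "x"]  # collinear pair
  b[, "y"] <- 2 * b[, "x"]
  expect_error(fit_lda(a, b), "singular")
  expect_error(fit_lda(matrix(rnorm(6), ncol = 2),
                       matrix(rnorm(20), ncol = 2)), "p \\+ 2")
})

test_that("package LDA agrees with MASS::lda up to scaling", {
  skip_if_not_installed("MASS")
  g <- make_groups(20)
  m <- fit_lda(g$a, g$b)
  X <- rbind(g$a, g$b)
  grp <- rep(c("a", "b"), each = nrow(g$a))
  mm <- MASS::lda(X, grouping = grp)
  w_pkg <- m$coefficients[c("u", "v")]
  w_mass <- drop(mm$scaling)
  ratio <- unname(w_pkg / w_mass)
  expect_equal(abs(ratio[1]), abs(ratio[2]), tolerance = 1e-8)
})
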