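test_that("two-means finds the optimal contiguous split", {
  cl <- two_means_1d(c(1, 2, 9, 10))
  expect_equal(as.character(cl$labels), c("lower", "lower", "higher",
                                          "higher"))
  expect_equal(unname(cl$sizes), c(2, 2))
  cl2 <- two_means_1d(c(0, 0, 0, 10))
  expect_equal(unname(cl2$sizes), c(3, 1))
  expect_equal(as.character(cl2$labels[4]), "higher")
  expect_error(two_means_1d(rep(3, 5)), "identical")
  expect_error(two_means_1d(4), "at least 2")
})

test_that("two-means matches an independent k-means oracle and its
           cluster ranges never overlap", {
  set.seed(42)
  for (i in 1:60) {
    n <- sample(3:200, 1)
    v <- c(rnorm(ceiling(n / 2), 0, 1), rnorm(floor(n / 2), 4, 1))
    cl <- two_means_1d(v)
    # ranges of the scalar clusters are disjoint (contiguity)
    expect_lt(cl$ranges$lower[2], cl$ranges$higher[1])
    expect_lt(cl$centers[["lower"]], cl$centers[["higher"]])
    # within-SS no worse than multi-start Lloyd k-means, and same
    # partition whenever kmeans found the optimum
    km <- kmeans(v, 2, nstart = 25)
    expect_lte(cl$within_ss, km$tot.withinss + 1e-8)
    if (abs(cl$within_ss - km$tot.withinss) < 1e-8) {
      expect_true(same_partition(cl$labels, km$cluster))
    }
  }
})

test_that("two-means tie-breaking prefers the balanced partition", {
  # symmetric instance: splits 1|3 and 3|1 cost the same; 2|2 is optimal
  cl <- two_means_1d(c(0, 1, 9, 10))
  expect_equal(unname(cl$sizes), c(2, 2))
})

test_that("Ward on trials 1-5 recovers duplicated-point structure and
           reduces to two-means on a single informative feature", {
  X <- rbind(matrix(rep(c(4, 6, 7, 8, 8), each = 4), 4),
             matrix(rep(c(8, 12, 14, 15, 15), each = 4), 4))
  cl <- ward_trials(X)
  expect_equal(as.character(cl$labels),
               rep(c("lower", "higher"), each = 4))
  # merge heights are monotone along the agglomeration
  expect_true(all(diff(cl$hclust$height) >= -1e-10))

  # only t3 varies: partition must agree with exact 1-D two-means
  set.seed(9)
  v <- c(rnorm(6, 4), rnorm(6, 10))
  X2 <- cbind(t1 = 5, t2 = 5, t3 = v, t4 = 5, t5 = 5)
  expect_true(same_partition(ward_trials(X2)$labels,
                             two_means_1d(v)$labels))
})

test_that("Ward agrees with the exhaustive bipartition oracle on small
           structured instances", {
  set.seed(1)
  for (i in 1:40) {
    n <- sample(3:6, 1)
    g1 <- sample(1:(n - 1), 1)
    mu <- c(rep(0, g1), rep(4, n - g1))
    X <- matrix(rnorm(n * 5, mean = rep(mu, 5)), n, 5)
    cl <- cutree(hclust(dist(X), "ward.D2"), 2)
    oracle <- best_bipartition(X)
    expect_true(same_partition(cl, oracle$labels))
    expect_equal(partition_sse(X, cl), oracle$sse, tolerance = 1e-10)
  }
})

test_that("two-means on fitted B3 recovers well-separated latent
           subgroups (gap >= 4, noise SD 1)", {
  spec <- default_population_spec()
  spec$b3_mean <- ifelse(spec$subgroup == "lower", 4, 8.5)
  co <- generate_cohort(spec, n_per_cell = 120, seed = 1)
  for (sx in c("M", "F")) {
    for (dg in c("control", "patient")) {
      sub <- co[co$sex == sx & co$diagnosis == dg, ]
      fits <- apply(as.matrix(sub[paste0("t", 1:5)]), 1,
                    fit_learning_curve, simplify = FALSE)
      conv <- vapply(fits, function(f) f$converged, TRUE)
      b3 <- vapply(fits[conv], function(f) f$params[["B3"]], 0.0)
      cl <- two_means_1d(b3)
      agree <- mean((cl$labels == "lower") ==
                      (sub$subgroup[conv] == "lower"))
      expect_gte(max(agree, 1 - agree), 0.9)
    }
  }
})

test_that("lower/higher naming follows the cluster means and is order
           invariant", {
  part <- c(1, 1, 2, 2)
  vals <- c(4.1, 4.3, 8.0, 8.2)
  lab <- label_clusters(part, vals)
  expect_equal(as.character(lab), c("lower", "lower", "higher", "higher"))
  # permuting the rows permutes the labels identically
  perm <- c(3, 1, 4, 2)
  lab2 <- label_clusters(part[perm], vals[perm])
  expect_equal(as.character(lab2), as.character(lab)[perm])
  expect_error(label_clusters(c(1, 1, 2, 2), c(2, 4, 1, 5)), "tied")
  expect_error(label_clusters(rep(1, 4), vals), "two clusters")
})
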