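test_that("similarity matrices match hand computation", {
  x <- rbind(c(0, 0), c(3, 4), c(6, 8))
  s <- similarity_matrix(x)
  expect_equal(s[1, 2], -5)
  expect_equal(s[1, 3], -10)
  expect_equal(s[2, 3], -5)
  expect_true(all(is.na(diag(s))))
  expect_equal(s, t(s))

  # spearman similarity is invariant to per-point monotone transforms
  set.seed(4)
  y <- matrix(runif(5 * 8), 5, 8)
  s1 <- similarity_matrix(y, metric = "spearman")
  s2 <- similarity_matrix(y^3, metric = "spearman")   # rank-preserving
  expect_equal(s1, s2, tolerance = 1e-12)

  expect_error(similarity_matrix(x[1:2, ]), "at least 3")
  xn <- x; xn[2, 1] <- NaN
  expect_error(similarity_matrix(xn), "NaN")
})

test_that("affinity propagation recovers separated blobs exactly", {
  set.seed(12)
  pts <- rbind(matrix(rnorm(40, 0, 0.3), 20, 2),
               matrix(rnorm(40, 5, 0.3), 20, 2),
               cbind(rnorm(20, 0, 0.3), rnorm(20, 5, 0.3)))
  truth <- rep(1:3, each = 20)
  s <- similarity_matrix(pts)
  res <- affinity_propagation(s, preference = median(s, na.rm = TRUE))
  expect_s3_class(res, "pvx_clusters")
  expect_equal(res$k, 3)
  expect_equal(adjusted_rand_index(res$assignments, truth), 1)
  expect_true(res$converged)
  # exemplars are assigned to their own cluster
  expect_equal(res$assignments[res$exemplars], seq_len(res$k))
  # deterministic
  res2 <- affinity_propagation(s, preference = median(s, na.rm = TRUE))
  expect_identical(res$assignments, res2$assignments)
})

test_that("preference bounds bracket the single-cluster/n-cluster regimes", {
  set.seed(21)
  pts <- rbind(matrix(rnorm(30, 0, 1), 15, 2),
               matrix(rnorm(30, 8, 1), 15, 2))
  s <- similarity_matrix(pts)
  b <- preference_bounds(s)
  expect_lt(b$p_min, b$p_max)
  expect_equal(b$p_max, max(s, na.rm = TRUE))
  # at p_max nearly every point is an exemplar; at p_min very few clusters
  hi <- affinity_propagation(s, b$p_max)
  expect_gte(hi$k, nrow(pts) - 2)
  lo <- affinity_propagation(s, b$p_min)
  expect_lte(lo$k, 2)
  # all-equal similarities are degenerate
  eq <- matrix(-1, 4, 4); diag(eq) <- NA
  expect_error(preference_bounds(eq), "degenerate")
})

test_that("knee point reproduces the documented example and an oracle", {
  # worked example: slow growth then explosion; the knee is at N = 5
  expect_equal(as.numeric(knee_point(c(1, 2, 3, 3, 4, 4, 5, 18, 60, 190))), 5)

  # agreement with the independent loop-based oracle on random curves
  for (seed in 1:12) {
    N <- random_knee_curve(seed)
    orc <- knee_oracle(N)
    if (is.null(orc)) {
      expect_error(knee_point(N), "no knee")
    } else {
      expect_equal(as.numeric(knee_point(N)), orc)
    }
  }

  # a perfectly linear curve has no curvature signal
  expect_error(knee_point(c(1, 2, 3, 4, 5, 6)), "no knee")
  expect_error(knee_point(c(2, 2, 2, 2, 2)), "no knee")
  expect_error(knee_point(c(1, 5, 20)), "at least 5")
})

test_that("automated preference scan tracks planted mixture structure", {
  # the knee heuristic is not an exact estimator (curve wobbles can shift
  # the selected preference), so assert protocol-level behavior: agreement
  # with the planted partition well above chance, averaged over replicates
  aris <- ks <- numeric(5)
  scan <- NULL
  for (i in 1:5) {
    g <- generate_gaussian_mixture(dims = 30, k = 3, n_per_cluster = 30,
                                   seed = 4000 + i)
    res <- suppressWarnings(auto_cluster(g$points))
    aris[i] <- adjusted_rand_index(res$assignments, g$labels)
    ks[i] <- res$k
    scan <- res$scan
  }
  expect_gt(mean(aris), 0.5)
  expect_gte(mean(ks), 2)
  expect_lte(mean(ks), 8)
  expect_equal(nrow(scan), 40)
  expect_true(all(diff(scan$preference) > 0))
  # cluster counts grow with preference across the scan
  expect_lt(scan$n_clusters[1], scan$n_clusters[40])
})

test_that("user-specified cluster counts are honoured by binary search", {
  set.seed(14)
  pts <- matrix(rnorm(60 * 4), 60, 4)
  for (k in c(3, 7)) {
    res <- auto_cluster(pts, user_k = k)
    expect_equal(res$k, k)
  }
})

test_that("duplicate points always land in the same cluster", {
  set.seed(8)
  pts <- rbind(matrix(rnorm(40, 0, 0.5), 20, 2),
               matrix(rnorm(40, 6, 0.5), 20, 2))
  pts <- rbind(pts, pts[3, ], pts[25, ])   # exact duplicates
  s <- similarity_matrix(pts)
  res <- affinity_propagation(s, preference = median(s, na.rm = TRUE))
  expect_equal(res$assignments[41], res$assignments[3])
  expect_equal(res$assignments[42], res$assignments[25])
})

test_that("adjusted Rand index hits its landmark values", {
  a <- rep(1:3, each = 10)
  expect_equal(adjusted_rand_index(a, a), 1)
  b <- a; b[a == 1] <- 4   # pure relabeling
  expect_equal(adjusted_rand_index(a, b), 1)
  # independent labelings hover near zero
  set.seed(5)
  vals <- replicate(50, adjusted_rand_index(sample(1:3, 60, TRUE),
                                            sample(1:3, 60, TRUE)))
  expect_lt(abs(mean(vals)), 0.05)
  # systematic disagreement goes negative
  expect_lt(adjusted_rand_index(c(1, 1, 2, 2), c(1, 2, 1, 2)), 0)
  expect_error(adjusted_rand_index(1:3, 1:4), "length")
})
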