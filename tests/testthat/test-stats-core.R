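test_that("normal_upper_quantile matches the erfc-bisection oracle", {
  expect_equal(normal_upper_quantile(0.5), 0)
  for (alpha in c(0.001, 0.025, 0.1, 0.4, 0.9)) {
    expect_lt(abs(normal_upper_quantile(alpha) -
                    oracle_upper_quantile(alpha)), 1e-6)
  }
  expect_equal(normal_upper_quantile(0.001), 3.090232, tolerance = 1e-6)
  expect_equal(normal_upper_quantile(0.025), 1.959964, tolerance = 1e-6)
  expect_error(normal_upper_quantile(0), "\\(0, 1\\)")
  expect_error(normal_upper_quantile(1), "\\(0, 1\\)")
})

test_that("quantile composed with the upper-tail CDF is the identity", {
  alphas <- seq(0.0005, 0.9995, length.out = 41)
  z <- normal_upper_quantile(alphas)
  back <- vapply(z, function(zz) pracma::erfc(zz / sqrt(2)) / 2, numeric(1))
  expect_lt(max(abs(back - alphas)), 1e-6)
})

test_that("one-sample t matches the integration oracle", {
  x <- c(0.55, 0.60, 0.65)
  res <- one_sample_t(x, 0.5)
  orc <- oracle_one_sample(x, 0.5)
  expect_equal(res$statistic, orc$t, tolerance = 1e-6)
  expect_equal(res$statistic, 3.4641016, tolerance = 1e-6)
  expect_equal(res$df, 2)
  expect_lt(abs(res$p_value - orc$p), 1e-6)
  expect_equal(res$p_value, 0.0742, tolerance = 1e-3)

  res0 <- one_sample_t(c(0.5, 0.5, 0.6, 0.4), 0.5)
  expect_equal(res0$statistic, 0)
  expect_equal(res0$p_value, 1)

  deg <- one_sample_t(c(0.6, 0.6), 0.5)
  expect_true(deg$degenerate)
  expect_true(is.na(deg$p_value))
  expect_error(one_sample_t(0.6, 0.5), "at least 2")
})

test_that("Welch t matches the oracle and is symmetric in p", {
  a <- c(1, 2, 3)
  b <- c(2, 3, 4)
  res <- welch_t(a, b)
  orc <- oracle_welch(a, b)
  expect_equal(res$statistic, -1.224745, tolerance = 1e-6)
  expect_equal(res$df, 4, tolerance = 1e-9)
  expect_lt(abs(res$p_value - orc$p), 1e-6)
  expect_equal(res$p_value, 0.2879, tolerance = 1e-3)

  expect_equal(welch_t(a, a)$statistic, 0)
  expect_equal(welch_t(a, a)$p_value, 1)
  expect_lt(welch_t(c(0, 0, 0.001), c(10, 10, 10.001))$p_value, 1e-6)
  expect_error(welch_t(1, a), "at least 2")

  # symmetry up to the sign of t, on random pairs
  set.seed(41)
  for (i in 1:20) {
    x <- rnorm(sample(3:8, 1))
    y <- rnorm(sample(3:8, 1), mean = runif(1, -1, 1))
    expect_equal(welch_t(x, y)$p_value, welch_t(y, x)$p_value)
    expect_equal(welch_t(x, y)$statistic, -welch_t(y, x)$statistic)
  }
})

test_that("BH adjustment equals the quadratic brute-force definition", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.5), 0.5)
  expect_equal(bh_adjust(c(0.001, 1)), c(0.002, 1))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(7)
  for (i in 1:200) {
    p <- runif(sample(1:12, 1))
    q <- bh_adjust(p)
    expect_equal(q, oracle_bh(p), tolerance = 1e-12)
    expect_true(all(q >= p))
    expect_equal(order(q[order(p)]), seq_along(p))  # order-preserving
  }
})

test_that("cosine distance covers proportional, orthogonal, mixed cases", {
  expect_equal(cosine_distance(c(1, 2, 3), c(2, 4, 6)), 0)
  expect_equal(cosine_distance(c(1, 0), c(0, 1)), 1)
  expect_equal(cosine_distance(c(1, 1), c(1, 0)), 1 - 1 / sqrt(2),
               tolerance = 1e-12)
  expect_error(cosine_distance(c(0, 0), c(1, 0)), "zero vector")
  expect_error(cosine_distance(1:3, 1:2), "equal")
  # matrix form agrees with the scalar form
  set.seed(8)
  m <- matrix(rnorm(20), nrow = 5,
              dimnames = list(paste0("p", 1:5), NULL))
  dm <- cosine_distance_matrix(m)
  expect_equal(dm["p2", "p4"], cosine_distance(m[2, ], m[4, ]),
               tolerance = 1e-12)
  expect_equal(dm, t(dm))
  expect_equal(diag(dm), setNames(rep(0, 5), rownames(m)))
})

test_that("average-linkage merges match a naive O(n^3) oracle", {
  expect_equal(hierarchical_cluster(matrix(c(0, 3, 3, 0), 2))$height, 3)
  set.seed(9)
  for (i in 1:10) {
    n <- 6
    pts <- matrix(rnorm(n * 3), nrow = n)
    d <- as.matrix(dist(pts))
    hc <- hierarchical_cluster(d, "average")
    expect_equal(sort(hc$height), oracle_average_heights(d),
                 tolerance = 1e-9)
  }
  # closest pair merges first
  d3 <- matrix(c(0, 1, 10, 1, 0, 9.5, 10, 9.5, 0), 3)
  hc3 <- hierarchical_cluster(d3)
  expect_equal(sort(hc3$merge[1, ]), c(-2, -1))
  # missing entries are rejected with imputation advice
  dna <- d3
  dna[1, 2] <- dna[2, 1] <- NA
  expect_error(hierarchical_cluster(dna), "missing")
})

test_that("dendrogram cuts partition the label set", {
  set.seed(10)
  pts <- matrix(rnorm(16), nrow = 8)
  d <- as.matrix(dist(pts))
  dimnames(d) <- list(letters[1:8], letters[1:8])
  hc <- hierarchical_cluster(d)
  expect_true(all(diff(hc$height) >= -1e-12))  # monotone heights
  for (k in 2:5) {
    ct <- stats::cutree(hc, k)
    expect_setequal(names(ct), letters[1:8])
    expect_equal(length(unique(ct)), k)
  }
  # newick serialization covers every leaf exactly once
  nwk <- as_newick(hc)
  expect_true(all(vapply(letters[1:8],
                         function(l) lengths(regmatches(nwk, gregexpr(l, nwk))) == 1L,
                         logical(1))))
})
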