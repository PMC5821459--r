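test_that("anchor normalization solves the two affine constraints", {
  v <- c(ORF1 = 0.75, A = 0.5, B = 0.25)  # median 0.5
  pt <- normalize_to_anchor(v, "ORF1")
  expect_equal(unname(pt$affine$x), c(2, -0.5))
  expect_equal(unname(pt$normalized[["ORF1"]]), 1)
  expect_equal(unname(pt$normalized[["A"]]), 0.5)

  # anchor 0.8, median 0.5: a = 5/3, b = -1/3, f(0.62) = 0.7
  v2 <- c(ORF1 = 0.8, A = 0.5, B = 0.62, C = 0.4, D = 0.3)
  pt2 <- normalize_to_anchor(v2, "ORF1")
  expect_equal(unname(pt2$normalized[["B"]]), 0.7, tolerance = 1e-12)

  # anchor already at 1 with median preserved: identity map
  v3 <- c(ORF1 = 1, A = 0.3, B = 0.5, C = 0.6, D = 0.2)
  pt3 <- normalize_to_anchor(v3, "ORF1")
  expect_equal(unname(pt3$affine$x), c(1, 0), tolerance = 1e-12)

  expect_error(normalize_to_anchor(v, "ORF9"), "not present")
  expect_error(normalize_to_anchor(c(ORF1 = 0.5, A = 0.6, B = 0.4), "ORF1"),
               "ill-defined")
})

test_that("normalization fixes the anchor at 1 and preserves the median", {
  set.seed(31)
  for (i in 1:100) {
    n <- sample(5:40, 1)
    v <- setNames(runif(n), paste0("P", seq_len(n)))
    anchor <- names(v)[which.max(abs(v - median(v)))]
    pt <- normalize_to_anchor(v, anchor)
    expect_lt(abs(pt$normalized[[anchor]] - 1), 1e-12)
    expect_lt(abs(median(pt$normalized) - median(v)), 1e-12)
  }
})

test_that("both axes of a swap pair are normalized independently", {
  sp <- data.frame(protein = c("ORF1", "A", "B", "C", "D"),
                   x = c(0.75, 0.5, 0.25, 0.6, 0.4),
                   y = c(0.8, 0.5, 0.62, 0.4, 0.55))
  pt <- normalize_to_anchor(sp, "ORF1")
  expect_equal(pt$normalized$x[pt$normalized$protein == "ORF1"], 1)
  expect_equal(pt$normalized$y[pt$normalized$protein == "ORF1"], 1)
  expect_equal(median(pt$normalized$x), median(sp$x), tolerance = 1e-12)
  expect_equal(median(pt$normalized$y), median(sp$y), tolerance = 1e-12)
})

test_that("cluster proximity metrics agree with hand arithmetic", {
  pts <- matrix(c(0, 0, 0, 0, 0.1, 0.2), ncol = 2,
                dimnames = list(c("a", "b", "c"), NULL))
  expect_equal(cluster_proximity(pts, c("a", "b", "c")), 0.2)
  expect_equal(cluster_proximity(pts, c("a", "b", "c"), "mean_pairwise"),
               (0.1 + 0.1 + 0.2) / 3, tolerance = 1e-12)
  expect_equal(cluster_proximity(pts, c("a", "b", "c"), "enclosing_radius"),
               0.1)
  expect_equal(cluster_proximity(rbind(pts, d = c(0, 0)), c("a", "d")), 0)
  expect_error(cluster_proximity(pts, c("a", "zz")), "absent")
})

test_that("exact enumeration matches the hand-enumerated 5-point example", {
  pts <- matrix(c(0, 0, 0, 1, 2, 0, 0.1, 0.2, 1, 2), ncol = 2,
                dimnames = list(paste0("p", 1:5), NULL))
  res <- cluster_proximity_pvalue(pts, c("p1", "p2", "p3"))
  expect_equal(res$proximity, 0.2)
  expect_equal(res$p_empirical, 0.1)  # 1 of the C(5,3) = 10 triples
  expect_equal(res$method, "exact")
  expect_equal(res$n_universe, 5L)
})

test_that("the unique tightest pair attains the minimal p of 1/C(n,2)", {
  set.seed(32)
  n <- 12
  pts <- matrix(runif(2 * n, 0, 10), ncol = 2,
                dimnames = list(paste0("p", seq_len(n)), NULL))
  dm <- as.matrix(dist(pts))
  diag(dm) <- Inf
  best <- arrayInd(which.min(dm), dim(dm))
  members <- rownames(pts)[best]
  res <- cluster_proximity_pvalue(pts, members)
  expect_equal(res$p_empirical, 1 / choose(n, 2))
})

test_that("exact enumeration equals a brute-force subset scan", {
  set.seed(33)
  for (i in 1:20) {
    n <- sample(8:30, 1)
    k <- sample(2:3, 1)
    pts <- matrix(runif(2 * n), ncol = 2,
                  dimnames = list(paste0("p", seq_len(n)), NULL))
    members <- sample(rownames(pts), k)
    res <- cluster_proximity_pvalue(pts, members)
    # independent brute force straight from the definition
    obs <- max(dist(pts[members, ]))
    hits <- sum(combn(n, k, FUN = function(idx) {
      max(dist(pts[idx, , drop = FALSE])) <= obs + 1e-12
    }))
    expect_equal(res$p_empirical, hits / choose(n, k))
  }
})

test_that("Monte-Carlo p agrees with exact p within binomial error", {
  set.seed(34)
  for (i in 1:5) {
    n <- 30
    pts <- matrix(runif(2 * n), ncol = 2,
                  dimnames = list(paste0("p", seq_len(n)), NULL))
    members <- sample(rownames(pts), 3)
    exact <- cluster_proximity_pvalue(pts, members)$p_empirical
    mc <- cluster_proximity_pvalue(pts, members, mode = "monte_carlo",
                                   n_samples = 1e4, seed = 100 + i)
    se <- sqrt(exact * (1 - exact) / 1e4)
    expect_lt(abs(mc$p_empirical - exact), 4 * se + 2 / 1e4)
    # reproducible under the same seed
    mc2 <- cluster_proximity_pvalue(pts, members, mode = "monte_carlo",
                                    n_samples = 1e4, seed = 100 + i)
    expect_equal(mc$p_empirical, mc2$p_empirical)
  }
})

test_that("p is invariant to rigid motion and non-member relabeling", {
  set.seed(35)
  n <- 15
  pts <- matrix(runif(2 * n), ncol = 2,
                dimnames = list(paste0("p", seq_len(n)), NULL))
  members <- c("p3", "p7", "p11")
  p0 <- cluster_proximity_pvalue(pts, members)$p_empirical
  theta <- 0.7
  rot <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2)
  pts2 <- sweep(pts %*% rot, 2, c(5, -2), "+")
  dimnames(pts2) <- dimnames(pts)
  expect_equal(cluster_proximity_pvalue(pts2, members)$p_empirical, p0)
  pts3 <- pts
  rownames(pts3) <- c(paste0("q", 1:2), "p3", paste0("q", 4:6), "p7",
                      paste0("q", 8:10), "p11", paste0("q", 12:15))
  expect_equal(cluster_proximity_pvalue(pts3, members)$p_empirical, p0)
})

test_that("the exact-enumeration cap directs callers to Monte Carlo", {
  set.seed(36)
  pts <- matrix(runif(60), ncol = 2,
                dimnames = list(paste0("p", 1:30), NULL))
  expect_error(cluster_proximity_pvalue(pts, c("p1", "p2", "p3"), cap = 100),
               "monte_carlo")
  expect_error(cluster_proximity_pvalue(pts, c("p1", "p2", "p3"),
                                        mode = "monte_carlo"), "seed")
})
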