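mk_profiles <- function(...) profile_set(list(...))

test_that("component distances concatenate shared experiments", {
  e1 <- matrix(c(1, 2, 2, 2), nrow = 2, byrow = TRUE,
               dimnames = list(c("A", "B"), NULL))
  ps <- mk_profiles(e1 = e1)
  comp <- pair_component_distances(ps, standardize = FALSE)
  expect_equal(comp$euclidean["A", "B"], 1)
  expect_equal(comp$cosine["A", "B"], 1 - 6 / (sqrt(5) * sqrt(8)),
               tolerance = 1e-12)
  # identical profiles: both components zero
  e2 <- matrix(c(1, 2, 1, 2), nrow = 2, byrow = TRUE,
               dimnames = list(c("A", "B"), NULL))
  comp2 <- pair_component_distances(mk_profiles(e = e2),
                                    standardize = FALSE)
  expect_equal(comp2$euclidean["A", "B"], 0)
  expect_equal(comp2$cosine["A", "B"], 0)
  # pairs sharing no experiment are flagged missing
  ea <- matrix(1:2, 1, dimnames = list("A", NULL))
  eb <- matrix(3:4, 1, dimnames = list("B", NULL))
  comp3 <- pair_component_distances(mk_profiles(x = ea, y = eb))
  expect_true(comp3$missing["A", "B"])
  expect_true(is.na(comp3$euclidean["A", "B"]))
  expect_equal(comp3$shared["A", "B"], 0L)
})

test_that("concatenation spans exactly the shared experiments", {
  set.seed(71)
  e1 <- matrix(rnorm(6), 3, dimnames = list(c("A", "B", "C"), NULL))
  e2 <- matrix(rnorm(4), 2, dimnames = list(c("A", "B"), NULL))
  comp <- pair_component_distances(mk_profiles(e1 = e1, e2 = e2),
                                   standardize = FALSE)
  expect_equal(comp$shared["A", "B"], 2L)
  expect_equal(comp$shared["A", "C"], 1L)
  expect_equal(comp$euclidean["A", "B"],
               sqrt(sum((c(e1["A", ], e2["A", ]) -
                           c(e1["B", ], e2["B", ]))^2)),
               tolerance = 1e-12)
  expect_equal(comp$euclidean["A", "C"],
               sqrt(sum((e1["A", ] - e1["C", ])^2)), tolerance = 1e-12)
})

test_that("Euclidean rescaling maps onto [delta, 0.9]", {
  expect_equal(rescale_euclidean(c(0, 5, 10)), c(0.001, 0.4505, 0.9),
               tolerance = 1e-12)
  expect_warning(out <- rescale_euclidean(c(3, 3, 3)), "equal")
  expect_equal(out, rep(0.9, 3))
  # missing values pass through untouched
  expect_equal(rescale_euclidean(c(0, NA, 10)), c(0.001, NA, 0.9))
})

test_that("missing pairs get component distance exactly 1 after rescaling", {
  ea <- matrix(c(1, 2, 5, 6, 2, 9), 3, byrow = TRUE,
               dimnames = list(c("A", "B", "C"), NULL))
  eb <- matrix(c(0, 1), 1, dimnames = list("D", NULL))
  comp <- pair_component_distances(mk_profiles(x = ea, y = eb))
  expect_error(assign_missing(comp), "rescale_euclidean")
  comp <- assign_missing(rescale_euclidean(comp))
  expect_equal(comp$euclidean["A", "D"], 1)
  expect_equal(comp$cosine["A", "D"], 1)
  expect_lte(comp$euclidean["A", "B"], 0.9)  # observed pairs capped at 0.9
  d <- combine_and_rescale(comp)
  expect_true(all(d >= 0 & d <= 1))
  expect_equal(unname(diag(d)), rep(0, 4))
})

test_that("the final distance is a monotone transform of the product", {
  set.seed(72)
  for (i in 1:10) {
    sim <- simulate_profile_set(n_modules = 3, proteins_per_module = 4,
                                sigma = 0.3, drop_fraction = 0.2,
                                seed = 1000 + i)
    comp <- assign_missing(rescale_euclidean(
      pair_component_distances(sim$profiles)))
    d <- combine_and_rescale(comp)
    off <- upper.tri(d)
    prod <- (comp$euclidean * pmax(comp$cosine, 1e-3))[off]
    expect_equal(cor(rank(prod), rank(d[off])), 1)
    expect_equal(d, t(d))
  }
})

test_that("removing an experiment only perturbs pairs that shared it", {
  set.seed(73)
  e1 <- matrix(rnorm(8), 4, dimnames = list(c("A", "B", "C", "D"), NULL))
  e2 <- matrix(rnorm(4), 2, dimnames = list(c("A", "B"), NULL))
  full <- pair_component_distances(mk_profiles(e1 = e1, e2 = e2),
                                   standardize = FALSE)
  part <- pair_component_distances(mk_profiles(e1 = e1),
                                   standardize = FALSE)
  # C-D never saw e2: their raw components are identical in both runs
  expect_equal(full$euclidean["C", "D"], part$euclidean["C", "D"])
  expect_equal(full$cosine["C", "D"], part$cosine["C", "D"])
  # A-B did share e2, so its Euclidean component changes
  expect_false(isTRUE(all.equal(full$euclidean["A", "B"],
                                part$euclidean["A", "B"])))
})

test_that("integration recovers planted modules", {
  sim <- simulate_profile_set(seed = 74)
  ic <- integrate_and_cluster(sim$profiles, k = 5)
  expect_gte(ari(ic$groups[names(sim$truth)], sim$truth), 0.8)
  # two far-separated modules are recovered perfectly
  sim2 <- simulate_profile_set(n_modules = 2, proteins_per_module = 6,
                               sigma = 0.02, seed = 75)
  ic2 <- integrate_and_cluster(sim2$profiles, k = 2)
  expect_equal(ari(ic2$groups[names(sim2$truth)], sim2$truth), 1)
})

test_that("a duplicated protein merges at height zero", {
  set.seed(76)
  base <- matrix(rnorm(12), 3, dimnames = list(c("A", "B", "C"), NULL))
  dup <- rbind(base, D = base["A", ])
  ic <- integrate_and_cluster(profile_set(list(e = dup)), k = 2)
  expect_equal(ic$distance["A", "D"], 0)
  expect_equal(min(ic$tree$height), 0)
  expect_equal(ic$groups[["A"]], ic$groups[["D"]])
})
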