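test_that("patristic distances are path sums of branch lengths", {
  tr <- ape::read.tree(text = "(A:1,B:1);")
  expect_equal(patristic_matrix(tr)["A", "B"], 2)

  tr3 <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  m <- patristic_matrix(tr3)
  expect_equal(m["A", "B"], 2)
  expect_equal(m["A", "C"], 4)
  expect_equal(m["B", "C"], 4)

  # agree with a naive path-enumeration oracle on random ultrametric trees,
  # which are also equidistant through the root
  for (seed in 1:3) {
    yt <- yule_tree(12, seed = seed)
    m <- patristic_matrix(yt)
    expect_equal(m, naive_patristic(yt), tolerance = 1e-12)
    expect_identical(m, t(m))
    expect_true(all(diag(m) == 0))
  }

  no_len <- ape::read.tree(text = "((A,B),C);")
  expect_error(patristic_matrix(no_len), "branch lengths")
  dup <- ape::read.tree(text = "((A:1,A:1):1,C:2);")
  expect_error(patristic_matrix(dup), "duplicate")
})

test_that("patristic matrices satisfy the four-point condition", {
  set.seed(8)
  for (rep in 1:5) {
    tr <- ape::rtree(10)  # non-ultrametric additive tree
    m <- patristic_matrix(tr)
    tips <- sample(tr$tip.label, 4)
    s <- sort(c(m[tips[1], tips[2]] + m[tips[3], tips[4]],
                m[tips[1], tips[3]] + m[tips[2], tips[4]],
                m[tips[1], tips[4]] + m[tips[2], tips[3]]))
    expect_equal(s[2], s[3], tolerance = 1e-10)
  }
})

test_that("trait-difference matrices are absolute differences of means", {
  m <- table3_matrix()
  expect_equal(m["batakorum_Palawan", "palawanensis_GreaterPalawan"], 5.61)
  expect_identical(m, t(m))

  x <- c(a = 2, b = 2, c = 5)
  expect_equal(trait_difference_matrix(x)["a", "b"], 0)
  # translation invariance
  expect_equal(trait_difference_matrix(x + 5), trait_difference_matrix(x))
  # linear scaling
  expect_equal(trait_difference_matrix(3 * x), 3 * trait_difference_matrix(x))
})

test_that("the dispersion statistic matches the fixture values", {
  m <- table3_matrix()
  pairs <- table3_pairs()
  expect_equal(delta_stat(m, pairs, "mean"), 1.746, tolerance = 1e-3)
  expect_equal(delta_stat(m, pairs, "median"), 1.10, tolerance = 1e-2)

  # all-equal matrix -> 0 under both aggregators
  flat <- matrix(2, 6, 6, dimnames = list(letters[1:6], letters[1:6]))
  diag(flat) <- 0
  p <- sympatry_assignment(rbind(c("a", "b"), c("c", "d")))
  expect_equal(delta_stat(flat, p, "mean"), 0)
  expect_equal(delta_stat(flat, p, "median"), 0)

  # relabeling invariance
  perm <- sample(rownames(m))
  expect_equal(delta_stat(m[perm, perm], pairs, "mean"),
               delta_stat(m, pairs, "mean"))

  # a single pair exhausts every pair of a 2-terminal matrix -> error
  two <- trait_difference_matrix(c(a = 1, b = 2))
  expect_error(delta_stat(two, rbind(c("a", "b")), "mean"), "allopatric")
})

test_that("sympatry assignments must be disjoint and known", {
  expect_error(sympatry_assignment(rbind(c("a", "b"), c("b", "c"))),
               "disjoint")
  expect_error(sympatry_assignment(rbind(c("a", "z")), labels = c("a", "b")),
               "not among")
  expect_error(sample_sympatry(letters[1:4], 3), "exceeds")
})

test_that("random sympatry is uniform over disjoint-pair configurations", {
  # 2 labels, k = 1: the single pair
  set.seed(1)
  p <- sample_sympatry(c("a", "b"), 1)
  expect_setequal(as.vector(p), c("a", "b"))

  # 4 labels, k = 2: exactly 3 configurations, hit uniformly
  set.seed(99)
  draws <- replicate(3000, {
    s <- sample_sympatry(letters[1:4], 2)
    paste(sort(apply(s, 1, function(r) paste(sort(r), collapse = ""))),
          collapse = "|")
  })
  tab <- table(draws)
  expect_identical(length(tab), 3L)
  expect_gt(chisq.test(tab)$p.value, 1e-3)

  # 12 labels, k = 3: the configuration space has 13,860 elements
  ex <- exact_test(table3_matrix(), 3, observed = 0, aggregator = "mean")
  expect_identical(ex$n_configurations, 13860L)
})

test_that("exact enumeration gives the expected tail probabilities", {
  m <- trait_difference_matrix(c(a = 0, b = 1, c = 3))
  # k = 1 over 3 labels: pairs ab, ac, bc with unique values; the statistic
  # is strictly increasing in the chosen entry, so the configuration picking
  # the largest entry is the unique maximum of the three
  obs_max <- delta_stat(m, rbind(c("a", "c")), "mean")
  ex <- exact_test(m, 1, observed = obs_max, aggregator = "mean")
  expect_equal(ex$p, 1 / 3)
  # observed below the minimum achievable statistic -> p = 1
  ex_min <- exact_test(m, 1, observed = min(ex$values) - 1,
                       aggregator = "mean")
  expect_equal(ex_min$p, 1)
  expect_error(exact_test(table3_matrix(), 3, 0, "mean", cap = 100), "cap")
})

test_that("a maximal sympatry configuration attains the minimal exact p", {
  # generic symmetric matrix (not trait-derived: 1-D traits make crossing
  # pairings tie exactly), so the maximum is attained by one configuration
  set.seed(4)
  m <- matrix(0, 8, 8, dimnames = list(letters[1:8], letters[1:8]))
  m[upper.tri(m)] <- runif(28)
  m <- m + t(m)
  ex_all <- exact_test(m, 2, observed = -Inf, aggregator = "mean")
  obs <- max(ex_all$values)
  ex <- exact_test(m, 2, obs, "mean")
  expect_equal(ex$p, 1 / ex$n_configurations)
})

test_that("Monte-Carlo permutation p converges to the exact enumeration", {
  m <- table3_matrix()
  pairs <- table3_pairs()
  obs <- delta_stat(m, pairs, "mean")
  p_exact <- exact_test(m, 3, obs, "mean")$p
  se <- sqrt(p_exact * (1 - p_exact) / 2000)
  for (seed in c(101, 202, 303)) {
    mc <- permutation_test(m, pairs, replicates = 2000, seed = seed,
                           aggregator = "mean")
    expect_lt(abs(mc$p - p_exact), 3 * se)
    expect_equal(mc$p_corrected,
                 (sum(mc$null_values >= mc$observed) + 1) / 2001)
    expect_length(mc$null_values, 2000L)
  }
})
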