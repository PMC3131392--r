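grid2 <- function(v) suitability_grid(matrix(v, 1, length(v)))

test_that("normalization produces a probability distribution, idempotently", {
  g <- normalize_grid(suitability_grid(matrix(2, 3, 4)))
  expect_true(g$normalized)
  expect_equal(unique(as.vector(g$values)), 1 / 12)

  vals <- matrix(c(1, 0, 1, 0, 1, 0), 2, 3)
  b <- normalize_grid(suitability_grid(vals))
  expect_equal(sort(unique(as.vector(b$values))), c(0, 1 / 3))

  expect_equal(normalize_grid(g), g)
  expect_error(normalize_grid(suitability_grid(matrix(0, 2, 2))),
               "all valid cells are zero")
})

test_that("minimum-training-presence thresholding matches a brute-force scan", {
  set.seed(5)
  vals <- matrix(runif(20 * 15), 15, 20)
  g <- suitability_grid(vals)
  pts <- data.frame(x = c(3, 10, 17), y = c(2, 7, 12))
  thr_grid <- min_presence_threshold(g, pts)
  thr <- attr(thr_grid, "threshold")
  expect_equal(thr, min(vals[cbind(pts$y + 1, pts$x + 1)]))
  expect_identical(thr_grid$values, matrix(as.numeric(vals >= thr), 15, 20))

  # all training at the maximum -> only maximal cells kept
  mx <- which(vals == max(vals), arr.ind = TRUE)
  top <- min_presence_threshold(g, data.frame(x = mx[, 2] - 1,
                                              y = mx[, 1] - 1))
  expect_equal(sum(top$values), nrow(mx))
  # training at the minimum -> everything kept
  mn <- which(vals == min(vals), arr.ind = TRUE)
  all1 <- min_presence_threshold(g, data.frame(x = mn[, 2] - 1,
                                               y = mn[, 1] - 1))
  expect_true(all(all1$values == 1))

  expect_error(min_presence_threshold(g, pts[0, ]), "empty")
})

test_that("overlap metrics hit their anchors and bounds", {
  a <- normalize_grid(grid2(c(0.5, 0.5)))
  b <- normalize_grid(grid2(c(1, 0)))
  expect_equal(schoener_d(a, b), 0.5)
  expect_equal(hellinger_i(a, b), 1 - 0.5 * ((sqrt(0.5) - 1)^2 + 0.5))
  expect_equal(hellinger_i(a, b), 0.7071, tolerance = 1e-4)

  expect_equal(schoener_d(a, a), 1)
  expect_equal(hellinger_i(a, a), 1)

  disj_a <- normalize_grid(grid2(c(1, 1, 0, 0)))
  disj_b <- normalize_grid(grid2(c(0, 0, 1, 1)))
  expect_equal(schoener_d(disj_a, disj_b), 0)
  expect_equal(hellinger_i(disj_a, disj_b), 0)

  expect_error(schoener_d(grid2(c(0.5, 0.5)), b), "normalized")
  mism <- normalize_grid(suitability_grid(matrix(1, 2, 2)))
  expect_error(schoener_d(a, mism), "identical dimensions")
})

test_that("I dominates D and both are symmetric and permutation-invariant", {
  set.seed(6)
  for (i in 1:200) {
    n <- sample(4:30, 1)
    a <- normalize_grid(grid2(runif(n) * rbinom(n, 1, 0.8)))
    b <- normalize_grid(grid2(runif(n) * rbinom(n, 1, 0.8)))
    D <- schoener_d(a, b); I <- hellinger_i(a, b)
    expect_gte(I, D - 1e-12)
    expect_true(D >= -1e-12 && I <= 1 + 1e-12)
    expect_equal(D, schoener_d(b, a))
    expect_equal(I, hellinger_i(b, a))
    # common cell permutation leaves both unchanged
    p <- sample(n)
    ap <- normalize_grid(grid2(a$values[1, p]))
    bp <- normalize_grid(grid2(b$values[1, p]))
    expect_equal(schoener_d(ap, bp), D)
    expect_equal(hellinger_i(ap, bp), I)
  }
})

test_that("degenerate fitters give the predicted null distributions", {
  L <- synthetic_landscape(12, 10, n_covariates = 1,
                           optima = rbind(0.5, 0.5), seed = 7)
  # binary map of the top half of species 1; the "other" species model
  binary <- L$suitability[[1]]
  binary$values <- matrix(as.numeric(binary$values >= median(binary$values)),
                          10, 12)
  other <- normalize_grid(binary)
  pres_mask <- binary$values == 1  # presence cells of the echoed map

  # fitter that ignores its points and returns the other species' binary
  # map: every random draw from the presence region has training minimum 1,
  # thresholding keeps the map unchanged, so null D = null I = 1 exactly
  echo_fitter <- function(points, covariates) binary
  bt <- background_similarity(other, observed_d = 0.8, observed_i = 0.8,
                              n_points = 10, m_mask = pres_mask,
                              covariates = L$covariates,
                              fitter = echo_fitter, replicates = 20,
                              seed = 8)
  expect_true(all(abs(bt$null_d - 1) < 1e-9))
  expect_true(all(abs(bt$null_i - 1) < 1e-9))
  # any observed < 1 sits below the whole null
  expect_equal(bt$p_upper_d, 1)
  expect_equal(bt$p_upper_i, 1)
  expect_equal(bt$p_lower_d, 0)

  # a fixed binary grid G != other: the null is a single point mass at
  # (D(G, other), I(G, other))
  fixed <- binary
  fixed$values <- matrix(rev(binary$values), 10, 12)
  fixed_fitter <- function(points, covariates) fixed
  bt2 <- background_similarity(other, observed_d = 0.5, observed_i = 0.5,
                               n_points = 5,
                               m_mask = fixed$values == 1,
                               covariates = L$covariates,
                               fitter = fixed_fitter, replicates = 15,
                               seed = 9)
  ref_d <- schoener_d(normalize_grid(fixed), other)
  expect_true(all(abs(bt2$null_d - ref_d) < 1e-9))
  expect_equal(bt2$failed, 0L)
  # tails are step functions at the point mass
  expect_equal(bt2$p_upper_d, as.numeric(ref_d >= 0.5))

  failing <- function(points, covariates) stop("no fit")
  expect_error(
    background_similarity(other, 0.5, 0.5, 3, pres_mask, L$covariates,
                          fitter = failing, replicates = 5, seed = 1),
    "all replicates failed")
})

test_that("identical species are detected as similar by the full test", {
  # 60 occurrences per species: the minimum-training-presence threshold is
  # noisy at small samples, which limits power (see the vignette), so the
  # detection property is demonstrated at a moderately informative size
  hits <- 0L
  for (trial in 1:20) {
    L <- synthetic_landscape(25, 20, n_covariates = 2,
                             optima = rbind(c(0.4, 0.6), c(0.4, 0.6)),
                             seed = 100 + trial)
    fit <- envelope_fitter()
    occA <- sample_occurrences(L$suitability[[1]], 60, seed = 200 + trial)
    occB <- sample_occurrences(L$suitability[[2]], 60, seed = 300 + trial)
    gA <- normalize_grid(min_presence_threshold(fit(occA, L$covariates), occA))
    gB <- normalize_grid(min_presence_threshold(fit(occB, L$covariates), occB))
    bt <- background_similarity(
      gA, schoener_d(gA, gB), hellinger_i(gA, gB),
      n_points = 60, m_mask = L$suitability[[2]],
      covariates = L$covariates, replicates = 60, seed = 400 + trial)
    # observed overlap in the upper tail of the null
    if (bt$p_lower_d >= 0.9 && bt$p_lower_i >= 0.9) hits <- hits + 1L
  }
  expect_gte(hits, 18L)
})
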