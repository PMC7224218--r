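# KDE hypervolumes: bandwidths, volume estimation against an analytic
# oracle, comparison metrics and their invariances.

test_that("silverman bandwidth follows the rule of thumb", {
  set.seed(1)
  x <- as.numeric(scale(rnorm(100)))  # exactly unit sd
  h <- silverman_bandwidth(matrix(x, ncol = 1))
  expect_equal(unname(h), 1.06 * 100^(-1 / 5), tolerance = 1e-12)
  expect_equal(unname(h), 0.4217, tolerance = 1e-3)
  y <- matrix(rnorm(300), ncol = 3)
  expect_equal(silverman_bandwidth(2 * y), 2 * silverman_bandwidth(y),
               tolerance = 1e-12)
  y[, 2] <- 7
  expect_error(silverman_bandwidth(y), "zero-variance")
  expect_error(silverman_bandwidth(y[1:2, ]), "at least 3")
})

test_that("H_100 covers the source points and nests H_75", {
  set.seed(2)
  x <- matrix(rnorm(4000), ncol = 2)
  hv100 <- build_hypervolume(x, p = 100, seed = 3)
  expect_gte(mean(nichechange:::hv_contains(hv100, x)), 0.99)
  hv75 <- build_hypervolume(x, p = 75, seed = 3)
  expect_lt(hv75$volume, hv100$volume)
  expect_gte(nrow(hv75$random_points), 100)
  expect_error(build_hypervolume(x, p = 0), "p must")
  expect_error(build_hypervolume(x, n_random = 10), "n_random")
})

test_that("H_75 volume matches the analytic area implied by the KDE threshold", {
  # oracle: for a large Gaussian sample the KDE is close to
  # N(mean, S + h^2 I); the area of {density >= t} is an ellipse,
  # pi * m * sqrt(det C) with m = -2 log(t * 2 pi * sqrt(det C)).
  rel_err <- vapply(1:10, function(s) {
    set.seed(s)
    x <- matrix(rnorm(4000), ncol = 2)
    hv <- build_hypervolume(x, p = 75, n_random = 20000, seed = s + 100)
    C <- stats::cov(x) + diag(hv$h^2)
    sd2 <- sqrt(det(C))
    m <- -2 * log(hv$threshold * 2 * pi * sd2)
    area <- pi * m * sd2
    hv$volume / area - 1
  }, numeric(1))
  expect_lt(abs(mean(rel_err)), 0.10)
})

test_that("identical clouds coincide; far-separated clouds are disjoint", {
  set.seed(4)
  x <- matrix(rnorm(2000), ncol = 2)
  h1 <- build_hypervolume(x, p = 75, seed = 9)
  h2 <- build_hypervolume(x, p = 75, seed = 9)
  cmp <- compare_hypervolumes(h1, h2)
  expect_gt(cmp$jaccard, 0.99)
  expect_lt(cmp$centroid_distance, 1e-9)
  expect_lt(cmp$unique_fraction_1, 1)
  far <- build_hypervolume(x + 100, p = 75, seed = 10)
  cmp2 <- compare_hypervolumes(h1, far)
  expect_equal(cmp2$jaccard, 0)
  expect_equal(cmp2$volumes[["intersection"]], 0)
  expect_equal(cmp2$unique_fraction_1, 100)
  expect_equal(cmp2$unique_fraction_2, 100)
  expect_gt(cmp2$minimum_distance, 50)
})

test_that("translation is recovered by the centroid distance within 2%", {
  delta <- 2
  err <- vapply(1:10, function(s) {
    set.seed(s)
    x <- matrix(rnorm(1600), ncol = 2)
    h1 <- build_hypervolume(x, p = 75, seed = s + 20)
    h2 <- build_hypervolume(sweep(x, 2, c(delta, 0), "+"), p = 75,
                            seed = s + 40)
    cmp <- compare_hypervolumes(h1, h2)
    cmp$centroid_distance / delta - 1
  }, numeric(1))
  expect_lt(abs(mean(err)), 0.02)
})

test_that("comparison metrics are symmetric and self-consistent", {
  set.seed(6)
  x <- matrix(rnorm(1200, sd = 1.3), ncol = 2)
  y <- sweep(matrix(rnorm(1200), ncol = 2), 2, c(1, 0.5), "+")
  h1 <- build_hypervolume(x, p = 75, seed = 1)
  h2 <- build_hypervolume(y, p = 75, seed = 2)
  ab <- compare_hypervolumes(h1, h2)
  ba <- compare_hypervolumes(h2, h1)
  expect_equal(ab$jaccard, ba$jaccard, tolerance = 1e-12)
  expect_equal(ab$centroid_distance, ba$centroid_distance, tolerance = 1e-12)
  expect_equal(ab$minimum_distance, ba$minimum_distance, tolerance = 1e-12)
  # unique_fraction_i + intersection / vol_i = 1 exactly as computed
  expect_equal(ab$unique_fraction_1 / 100 +
                 ab$volumes[["intersection"]] / ab$volumes[["niche1"]], 1,
               tolerance = 1e-12)
  # union = v1 + v2 - intersection
  expect_equal(ab$volumes[["union"]],
               ab$volumes[["niche1"]] + ab$volumes[["niche2"]] -
                 ab$volumes[["intersection"]], tolerance = 1e-12)
  # order invariance of the build (same seed, shuffled rows)
  h1b <- build_hypervolume(x[sample(nrow(x)), ], p = 75, seed = 1)
  expect_equal(h1b$volume, h1$volume, tolerance = 1e-12)
  # guard rails
  x3 <- matrix(rnorm(300), ncol = 3)
  expect_error(compare_hypervolumes(h1, build_hypervolume(x3, p = 75)),
               "dimensionality")
  expect_error(compare_hypervolumes(h1, build_hypervolume(y, p = 100)),
               "quantiles")
})

test_that("jaccard decreases monotonically with translation distance", {
  meds <- vapply(c(0, 1, 2, 3), function(d) {
    js <- vapply(1:6, function(s) {
      set.seed(s)
      x <- matrix(rnorm(1000), ncol = 2)
      h1 <- build_hypervolume(x, p = 75, seed = s)
      h2 <- build_hypervolume(sweep(x, 2, c(d, 0), "+"), p = 75,
                              seed = s + 50)
      compare_hypervolumes(h1, h2)$jaccard
    }, numeric(1))
    median(js)
  }, numeric(1))
  expect_true(all(diff(meds) < 0))
})
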