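# ENM data preparation, learners, evaluation, ensembling, projection
# and clamping.

test_that("thinning keeps one record per cell and matches a grid-hash oracle", {
  occ <- data.frame(lon = c(0.001, 0.002, 1, 2), lat = c(0.001, 0.002, 1, 2))
  expect_message(th <- thin_records(occ, cell_size_km = 5), "thinned")
  expect_equal(nrow(th), 3)
  # k records in k distinct cells are all retained
  occ2 <- data.frame(lon = seq(0, 10, by = 1), lat = seq(0, 10, by = 1))
  expect_equal(nrow(suppressMessages(thin_records(occ2, 5))), 11)
  # 1000 random points vs brute-force hash
  set.seed(1)
  occ3 <- data.frame(lon = runif(1000, 0, 2), lat = runif(1000, 0, 2))
  th3 <- suppressMessages(thin_records(occ3, 5))
  deg <- 5 / 111.32
  hash <- paste(floor(occ3$lon / deg), floor(occ3$lat / deg))
  oracle <- vapply(split(seq_len(1000), hash), min, numeric(1))
  expect_setequal(rownames(th3), as.character(sort(oracle)))
  expect_error(thin_records(occ3[0, ], 5), "empty")
})

test_that("correlation filter applies the <= 0.7 rule", {
  set.seed(2)
  x <- rnorm(200)
  expect_equal(correlation_filter(data.frame(x = x, y = 2 * x)), "x")
  # a pair at exactly r = 0.7 is kept
  a <- as.numeric(scale(rnorm(200)))
  b <- as.numeric(scale(residuals(lm(rnorm(200) ~ a))))
  y <- 0.7 * a + sqrt(1 - 0.49) * b
  expect_equal(abs(cor(a, y)), 0.7, tolerance = 1e-12)
  expect_equal(correlation_filter(data.frame(a = a, y = y)), c("a", "y"))
  ind <- as.data.frame(matrix(rnorm(600), ncol = 3))
  expect_equal(correlation_filter(ind), names(ind))
  expect_error(correlation_filter(data.frame(a = a, k = rep(1, 200))),
               "constant")
})

test_that("pseudo-absence sampling avoids presence cells and is seeded", {
  set.seed(3)
  bg <- data.frame(lon = runif(2000, 0, 10), lat = runif(2000, 0, 10))
  occ <- bg[1:200, ]
  pa1 <- sample_pseudo_absences(bg, occ, n = 500, cell_size = 0.2, seed = 4)
  pa2 <- sample_pseudo_absences(bg, occ, n = 500, cell_size = 0.2, seed = 4)
  expect_identical(pa1, pa2)
  key <- function(d) paste(floor(d$lon / 0.2), floor(d$lat / 0.2))
  expect_length(intersect(key(pa1), key(occ)), 0)
  expect_error(sample_pseudo_absences(bg, occ, n = 5000, cell_size = 0.2),
               "eligible")
})

test_that("split plans are stratified and partition the remainder", {
  pa <- toy_pa(n = 100, seed = 5)
  plan <- split_dataset(pa, n_repeats = 4, seed = 6)
  expect_equal(sum(pa$y[plan$eval_idx] == 1), 30)
  expect_equal(sum(pa$y[plan$eval_idx] == 0), 30)
  rest <- setdiff(seq_along(pa$y), plan$eval_idx)
  for (rp in plan$repeats) {
    expect_setequal(c(rp$train, rp$test), rest)
    expect_length(intersect(rp$train, rp$test), 0)
    # class proportions preserved within one record
    for (idx in list(rp$train, rp$test))
      expect_lte(abs(sum(pa$y[idx] == 1) - sum(pa$y[idx] == 0)), 1)
  }
})

test_that("prevalence weights balance the classes", {
  pa <- make_pa_dataset(data.frame(a = rnorm(30)),
                        data.frame(a = rnorm(300)), "invaded")
  expect_equal(sum(pa$weights[pa$y == 1]), sum(pa$weights[pa$y == 0]),
               tolerance = 1e-9)
})

test_that("every shipped learner separates a separable toy problem", {
  pa <- toy_pa(n = 50, seed = 7)
  for (ls in default_learners()) {
    set.seed(1)
    fit <- suppressWarnings(ls$fit(pa$env, pa$y, pa$weights))
    pred <- ls$predict(fit, pa$env)
    expect_true(all(pred >= 0 & pred <= 1), info = ls$name)
    expect_equal(eval_scores(pred, pa$y)$auc, 1, tolerance = 1e-9,
                 info = ls$name)
  }
})

test_that("label-shuffled data scores near-random test AUC", {
  set.seed(8)
  env <- data.frame(env1 = rnorm(500), env2 = rnorm(500))
  y <- sample(rep(0:1, each = 250))
  pa <- make_pa_dataset(env[y == 1, , drop = FALSE],
                        env[y == 0, , drop = FALSE], "native")
  plan <- split_dataset(pa, n_repeats = 3, seed = 9)
  ms <- suppressWarnings(fit_members(pa, plan, seed = 10))
  aucs <- vapply(ms$members, function(m) m$scores$auc, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.07)
})

test_that("contract violations are rejected with a log entry", {
  bad <- learner_spec("bad",
                      fit = function(env, y, weights) list(),
                      predict = function(fit, env) rep(2, nrow(env)))
  pa <- toy_pa(n = 40, seed = 11)
  plan <- split_dataset(pa, n_repeats = 2, seed = 12)
  expect_warning(ms <- fit_members(pa, plan,
                                   list(bad, learner_glm()), seed = 13),
                 "rejected")
  expect_true(all(grepl("bad", ms$log)))
  expect_equal(length(ms$members), 2)  # glm survives both repeats
  expect_error(fit_members(pa, plan, list(bad)), "failed")
})

test_that("AUC and TSS behave at the printed limits and match the pair oracle", {
  s <- eval_scores(c(0.9, 0.8, 0.7, 0.2, 0.1, 0.05), c(1, 1, 1, 0, 0, 0))
  expect_equal(s$auc, 1)
  expect_equal(s$tss, 1)
  expect_equal(s$tss, s$sensitivity + s$specificity - 1)
  cst <- eval_scores(rep(0.4, 10), rep(0:1, 5))
  expect_equal(cst$auc, 0.5)
  expect_equal(cst$tss, 0)
  expect_equal(cst$auc_band, "no-better-than-random")
  # hand-scored six points vs pair counting
  sc <- c(0.9, 0.3, 0.8, 0.8, 0.2, 0.6); y <- c(1, 1, 0, 1, 0, 0)
  expect_equal(eval_scores(sc, y)$auc, oracle_auc(sc, y), tolerance = 1e-12)
  # property: rank AUC equals the oracle on random small datasets with ties
  set.seed(14)
  for (i in 1:20) {
    n <- sample(10:50, 1)
    y <- c(0, 1, rbinom(n - 2, 1, 0.5))
    sc <- round(runif(n), sample(1:3, 1))  # induces ties
    expect_equal(eval_scores(sc, y)$auc, oracle_auc(sc, y),
                 tolerance = 1e-12)
  }
  expect_error(eval_scores(runif(5), rep(1, 5)), "single class")
})

test_that("TSS weighting of the ensemble follows max(TSS, 0)", {
  mk <- function(tss, const) {
    structure(list(
      spec = learner_spec(paste0("c", const),
                          fit = function(env, y, weights) const,
                          predict = function(fit, env) rep(fit, nrow(env))),
      fit = const, repeat_id = 1,
      scores = structure(list(auc = 0.5, tss = tss), class = "eval_scores")),
      class = "suit_model")
  }
  ms <- structure(list(members = list(mk(0.6, 0.2), mk(0.3, 0.8),
                                      mk(-0.1, 1.0)),
                       log = character(0), range_label = "native"),
                  class = "member_set")
  ens <- build_ensemble(ms)
  expect_equal(ens$weights, c(0.6, 0.3, 0))
  env <- data.frame(a = 1:3)
  pred <- nichechange:::predict_suitability(ens, env)
  expect_equal(pred, rep((2 / 3) * 0.2 + (1 / 3) * 0.8, 3), tolerance = 1e-12)
  # single member: ensemble is the member
  one <- structure(list(members = list(mk(0.5, 0.7)), log = character(0),
                        range_label = "native"), class = "member_set")
  expect_equal(nichechange:::predict_suitability(build_ensemble(one), env),
               rep(0.7, 3))
  # equal TSS: arithmetic mean
  two <- structure(list(members = list(mk(0.4, 0.2), mk(0.4, 0.6)),
                        log = character(0), range_label = "native"),
                   class = "member_set")
  expect_equal(nichechange:::predict_suitability(build_ensemble(two), env),
               rep(0.4, 3))
  none <- structure(list(members = list(mk(-0.2, 0.1)), log = character(0),
                         range_label = "native"), class = "member_set")
  expect_error(build_ensemble(none), "positive TSS")
})

test_that("raster projection agrees with point-wise prediction and keeps NAs", {
  pa <- toy_pa(n = 50, seed = 15)
  plan <- split_dataset(pa, n_repeats = 2, seed = 16)
  ms <- suppressWarnings(fit_members(pa, plan,
                                     list(learner_glm()), seed = 17))
  ens <- build_ensemble(ms)
  m1 <- matrix(rnorm(20), 4, 5); m2 <- matrix(rnorm(20), 4, 5)
  m1[2, 3] <- NA
  st <- env_stack(list(env1 = m1, env2 = m2))
  proj <- project_suitability(ens, st)
  expect_true(is.na(proj[2, 3]))
  expect_equal(dim(proj), c(4, 5))
  df <- data.frame(env1 = m1[1, 1], env2 = m2[1, 1])
  expect_equal(proj[1, 1], nichechange:::predict_suitability(ens, df),
               tolerance = 1e-12)
  # constant environment -> constant suitability
  stc <- env_stack(list(env1 = matrix(1, 3, 3), env2 = matrix(2, 3, 3)))
  pc <- project_suitability(ens, stc)
  expect_equal(max(pc) - min(pc), 0)
})

test_that("clamping masks flag values outside the calibration range", {
  tr <- data.frame(a = runif(100, 0, 1), b = runif(100, 0, 1))
  inside <- data.frame(a = runif(50, 0.1, 0.9), b = runif(50, 0.1, 0.9))
  cm <- clamping_mask(tr, inside)
  expect_false(any(cm$combined))
  shifted <- data.frame(a = runif(50, 2, 3), b = runif(50, 0.1, 0.9))
  cm2 <- clamping_mask(tr, shifted)
  expect_equal(unname(cm2$fractions["a"]), 1)
  expect_equal(unname(cm2$fractions["b"]), 0)
  # mixed case vs brute force; boundary equality is not clamped
  tgt <- data.frame(a = c(min(tr$a), max(tr$a), -1, 0.5),
                    b = c(0.5, 2, 0.5, 0.5))
  cm3 <- clamping_mask(tr, tgt)
  expect_equal(cm3$combined, c(FALSE, TRUE, TRUE, FALSE))
  expect_equal(cm3$fraction_combined, 0.5)
  expect_error(clamping_mask(tr, tgt["a"]), "lacks")
})
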