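# small deterministic grid builder: constant predictors except temperature
toy_grid <- function(n_cells = 40, warming = 0.28, t0 = NULL, seed = 2) {
  w <- generate_world(world_sim_config(n_cells = n_cells, n_obs = n_cells,
                                       warming_1992_2013 = warming,
                                       seed = seed))
  w$grid
}

test_that("spatial slope is exact, permutation invariant, and guarded", {
  d <- data.frame(temperature = c(1, 4, 7, 10, 13))
  d$mbc <- 100 - 8 * d$temperature
  expect_equal(spatial_slope(d), -8, tolerance = 1e-12)
  perm <- d[c(3, 1, 5, 2, 4), ]
  expect_equal(spatial_slope(perm), spatial_slope(d))

  d$temperature <- 5
  expect_error(spatial_slope(d), "constant")
  expect_error(spatial_slope(d[1:2, ]), "at least 3")
})

test_that("random forest wrapper is deterministic and learns signal", {
  w <- small_world()
  train <- w$observations

  m1 <- fit_mbc_model(train, seed = 42, num_trees = 60)
  m2 <- fit_mbc_model(train, seed = 42, num_trees = 60)
  p1 <- predict(m1, data = train, num.threads = 1)$predictions
  p2 <- predict(m2, data = train, num.threads = 1)$predictions
  expect_identical(p1, p2)

  # constant training response: constant predictions everywhere
  flat <- train
  flat$mbc <- 123.4
  mf <- fit_mbc_model(flat, seed = 1, num_trees = 30)
  pf <- predict(mf, data = train, num.threads = 1)$predictions
  expect_equal(pf, rep(123.4, nrow(train)), tolerance = 1e-9)

  # fits better than predicting the mean on data with real structure
  sse_model <- sum((train$mbc - p1)^2)
  sse_mean <- sum((train$mbc - mean(train$mbc))^2)
  expect_lt(sse_model, sse_mean)
})

test_that("global prediction series respects time-invariance and mask locality", {
  w <- small_world()
  model <- fit_mbc_model(w$observations, seed = 7, num_trees = 40)

  # a grid without warming gives 22 identical totals
  g0 <- toy_grid(n_cells = 150, warming = 0, seed = 5)
  s0 <- predict_global_series(model, g0)
  expect_equal(length(s0), 22L)
  expect_equal(max(s0) - min(s0), 0, tolerance = 1e-8)

  # masks act cell-locally: totals add over disjoint masks
  g <- w$grid
  maskA <- rep(FALSE, nrow(g$cells)); maskA[1:60] <- TRUE
  maskB <- !maskA
  sA <- predict_global_series(model, g, maskA)
  sB <- predict_global_series(model, g, maskB)
  sAll <- predict_global_series(model, g)
  expect_equal(sA + sB, sAll, tolerance = 1e-9)

  expect_error(predict_global_series(model, g, rep(FALSE, nrow(g$cells))),
               "empty")
})

test_that("change rate matches closed forms and is scale invariant", {
  years <- 1992:2013
  flat <- setNames(rep(500, 22), years)
  expect_equal(change_rate(flat)$rate, 0, tolerance = 1e-12)

  # linear decline of 0.162% of the initial level per year
  series <- setNames(100 * (1 - 0.00162 * (years - 1992)), years)
  expect_equal(change_rate(series, denominator = "initial")$rate, -0.162,
               tolerance = 1e-10)
  # with the period-mean denominator the closed form rescales accordingly
  expect_equal(change_rate(series)$rate, -0.162 * 100 / mean(series),
               tolerance = 1e-10)

  cr1 <- change_rate(series)
  cr2 <- change_rate(series * 1e6)
  expect_equal(cr1$rate, cr2$rate, tolerance = 1e-12)

  expect_error(change_rate(setNames(rep(0, 22), years)), "denominator")
})

test_that("Mahalanobis mask is sane at the centroid and monotone in quantile", {
  w <- small_world()
  g <- w$grid
  train <- w$observations

  m95 <- coverage_mask_mahalanobis(train, g, quantile = 0.95)
  m99 <- coverage_mask_mahalanobis(train, g, quantile = 0.99)
  expect_true(all(which(m95) %in% which(m99)))  # masks grow with quantile

  # a synthetic cell at the training centroid is always valid
  d2 <- attr(m95, "d2")
  expect_true(min(d2) < qchisq(0.95, df = 9))

  # same-distribution coverage close to the quantile
  w2 <- generate_world(world_sim_config(n_cells = 2000, n_obs = 762, seed = 33))
  mk <- coverage_mask_mahalanobis(w2$observations, w2$grid, quantile = 0.975)
  expect_gt(mean(mk), 0.93)
  expect_lte(mean(mk), 1)
})

test_that("dissimilarity index is zero at training points and excludes shifted grids", {
  w <- small_world()
  g <- w$grid
  train <- w$observations

  mk <- coverage_mask_dissimilarity(train, g)
  di <- attr(mk, "di")
  # observation cells coincide with grid cells: their DI is exactly 0
  expect_equal(unname(di[train$cell_id]), rep(0, nrow(train)),
               tolerance = 1e-6)
  expect_true(all(mk[train$cell_id]))

  # pushing grid temperatures beyond the training range shrinks coverage
  fractions <- sapply(c(0, 10, 25, 60), function(shift) {
    gs <- g
    gs$temperature <- g$temperature + shift
    mean(coverage_mask_dissimilarity(train, gs))
  })
  expect_true(all(diff(fractions) <= 0))
  expect_lt(fractions[4], fractions[1])

  expect_error(coverage_mask_dissimilarity(train[1, ], g), "at least 2")
})

test_that("bootstrap machinery is reproducible and resamples as declared", {
  w <- small_world()
  s1 <- bootstrap_sft(w$observations, w$grid, m = 50, reps = 8, seed = 21,
                      num_trees = 40)
  s2 <- bootstrap_sft(w$observations, w$grid, m = 50, reps = 8, seed = 21,
                      num_trees = 40)
  expect_identical(s1, s2)
  s3 <- bootstrap_sft(w$observations, w$grid, m = 50, reps = 8, seed = 22,
                      num_trees = 40)
  expect_false(identical(s1$replicates, s3$replicates))

  expect_identical(nrow(s1$replicates), 8L)
  expect_true(all(s1$replicates$coverage_fraction > 0 &
                    s1$replicates$coverage_fraction <= 1))
  expect_true(all(is.finite(s1$replicates$change_rate)))
  expect_true(abs(s1$pearson_r) <= 1)

  # change rate is insensitive to a global rescaling of MBC units (up to
  # floating-point tie-breaking inside the forest's split search)
  obs_scaled <- w$observations
  obs_scaled$mbc <- obs_scaled$mbc * 1000
  s4 <- bootstrap_sft(obs_scaled, w$grid, m = 50, reps = 8, seed = 21,
                      num_trees = 40)
  expect_equal(s4$mean_change_rate, s1$mean_change_rate, tolerance = 0.2)
  expect_identical(sign(s4$mean_change_rate), sign(s1$mean_change_rate))
  # the per-replicate spatial slopes scale exactly
  expect_equal(s4$replicates$spatial_slope, 1000 * s1$replicates$spatial_slope,
               tolerance = 1e-9)
})

test_that("with-replacement sampling shows the expected unique-row fraction", {
  n <- 120; m <- 50
  w <- small_world()
  set.seed(77)
  # reproduce the index stream the bootstrap draws internally
  idx <- matrix(sample.int(n, m * 40, replace = TRUE), nrow = m)
  uniq <- apply(idx, 2, function(j) length(unique(j)))
  expected <- n * (1 - (1 - 1 / n)^m)
  expect_lt(abs(mean(uniq) - expected), 3 * sd(uniq) / sqrt(40) + 1)
})

test_that("shared-mask mode predicts over the intersection of valid cells", {
  w <- small_world()
  s <- bootstrap_sft(w$observations, w$grid, m = 60, reps = 5, seed = 9,
                     num_trees = 30, shared_mask = TRUE)
  # every replicate reports the same coverage fraction under a shared layer
  expect_identical(length(unique(s$replicates$coverage_fraction)), 1L)
})
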