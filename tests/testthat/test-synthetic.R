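test_that("identical seeds reproduce identical tables; different seeds differ", {
  cfg <- warming_sim_config(n_pairs = 50, bin_effects = c("1-2" = 0.1), seed = 5)
  expect_identical(generate_warming_pairs(cfg), generate_warming_pairs(cfg))
  cfg2 <- warming_sim_config(n_pairs = 50, bin_effects = c("1-2" = 0.1), seed = 6)
  expect_false(identical(generate_warming_pairs(cfg),
                         generate_warming_pairs(cfg2)))

  lt <- generate_longterm_series(seed = 3)
  expect_identical(lt, generate_longterm_series(seed = 3))
  expect_false(identical(lt, generate_longterm_series(seed = 4)))

  w <- generate_world(world_sim_config(n_cells = 200, n_obs = 50, seed = 8))
  w2 <- generate_world(world_sim_config(n_cells = 200, n_obs = 50, seed = 8))
  expect_identical(w, w2)
})

test_that("warming-pair generator respects its ground truth", {
  # no effect, no noise: LN(RR) collapses to zero
  cfg <- warming_sim_config(n_pairs = 40, bin_effects = c("2-3" = 0),
                            between_study_sd = 0, within_sd_frac = 1e-9,
                            within_sd_sdlog = 0, seed = 1)
  rec <- generate_warming_pairs(cfg)
  expect_equal(log(rec$mbc_warmed / rec$mbc_control), rep(0, 40),
               tolerance = 1e-6)

  # Monte-Carlo recovery of a bin effect within 3 SE
  cfg <- warming_sim_config(n_pairs = 200, bin_effects = c("4-5" = -0.3),
                            seed = 2)
  rec <- generate_warming_pairs(cfg)
  lnrr <- log(rec$mbc_warmed / rec$mbc_control)
  se <- sd(lnrr) / sqrt(length(lnrr))
  expect_lt(abs(mean(lnrr) - (-0.3)), 3 * se)
  # magnitudes stay inside their bin
  expect_true(all(rec$warming_magnitude >= 4 & rec$warming_magnitude <= 5))

  # total suppression: no surviving record above the cutoff
  cfg <- warming_sim_config(n_pairs = 100, bin_effects = c("1-2" = 0),
                            suppress_prob = 1, suppress_side = "high",
                            suppress_cutoff = 0, seed = 3)
  rec <- generate_warming_pairs(cfg)
  expect_true(all(log(rec$mbc_warmed / rec$mbc_control) <= 0))
  expect_lt(nrow(rec), 100)

  expect_error(warming_sim_config(bin_effects = numeric(0)), "non-empty")
  expect_error(warming_sim_config(n_pairs = 3,
                                  bin_effects = c("1-2" = 0, "2-3" = 0)),
               "2 pairs per")
})

test_that("per-bin LN(RR) is symmetric about its generating mean", {
  cfg <- warming_sim_config(n_pairs = 2000, bin_effects = c("1-2" = 0.1),
                            seed = 12)
  rec <- generate_warming_pairs(cfg)
  lnrr <- log(rec$mbc_warmed / rec$mbc_control)
  skew <- mean((lnrr - mean(lnrr))^3) / sd(lnrr)^3
  expect_lt(abs(skew), 0.15)
})

test_that("long-term generator recovers its temporal sensitivity", {
  # noiseless: exact recovery at every site
  lt <- generate_longterm_series(n_sites = 4, temp_sensitivity = -5,
                                 noise_sd = 0, seed = 5)
  tab <- longterm_slopes(lt)
  expect_equal(tab$slope, rep(-5, 4), tolerance = 1e-9)

  # zero sensitivity, no noise: MBC constant within each site
  lt0 <- generate_longterm_series(n_sites = 3, temp_sensitivity = 0,
                                  noise_sd = 0, seed = 6)
  spread <- tapply(lt0$mbc, lt0$site_id, function(x) diff(range(x)))
  expect_equal(as.numeric(spread), rep(0, 3), tolerance = 1e-12)

  # noisy: mean recovered slope within 3 SE of truth across 50 sites
  lt <- generate_longterm_series(n_sites = 50, temp_sensitivity = -5,
                                 noise_sd = 2, seed = 7)
  tab <- longterm_slopes(lt)
  se <- sd(tab$slope) / sqrt(nrow(tab))
  expect_lt(abs(mean(tab$slope) - (-5)), 3 * se)

  expect_error(generate_longterm_series(years_per_site = c(2, 5)), "within")
})

test_that("world generator decouples spatial and temporal sensitivity", {
  cfg <- world_sim_config(n_cells = 1500, n_obs = 600,
                          spatial_slope_true = -8,
                          temporal_sensitivity_true = 0, seed = 14)
  w <- generate_world(cfg)

  # the grid warms by exactly the configured total
  dT <- mean(w$grid$temperature[, "2013"]) - mean(w$grid$temperature[, "1992"])
  expect_equal(dT, 0.28, tolerance = 1e-12)

  # with zero temporal sensitivity the true global series is flat
  ts <- true_global_series(w$grid)
  expect_equal(max(ts) - min(ts), 0, tolerance = 1e-6)

  # refitting the generating relation recovers the spatial slope within 3 SE
  fit <- lm(mbc ~ temperature, data = w$observations)
  est <- coef(fit)[["temperature"]]
  se <- summary(fit)$coefficients["temperature", "Std. Error"]
  expect_lt(abs(est - (-8)), 3 * se)

  # a nonzero temporal sensitivity appears in the true series trend
  cfg2 <- world_sim_config(n_cells = 500, n_obs = 200,
                           temporal_sensitivity_true = -30, seed = 15)
  w2 <- generate_world(cfg2)
  ts2 <- true_global_series(w2$grid)
  tot_change <- unname(ts2["2013"] - ts2["1992"])
  expect_equal(tot_change, -30 * 0.28 * 500, tolerance = 1e-6)

  expect_error(world_sim_config(n_cells = 10, n_obs = 20), "exceed")
})

test_that("observations sample the baseline grid truth", {
  w <- small_world()
  g <- w$grid
  idx <- w$observations$cell_id
  expect_true(all(idx %in% g$cells$cell_id))
  expect_false(anyDuplicated(idx) > 0)
  expect_equal(w$observations$mbc, g$truth$mbc0[idx])
  expect_true(all(w$observations$mbc > 0))
  expect_identical(levels(w$observations$land_cover),
                   levels(g$cells$land_cover))
})
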