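test_that("generators are bit-identical under the same seed and differ across seeds", {
  a <- simulate_inputs(5)
  b <- simulate_inputs(5)
  a$cfg <- b$cfg <- NULL
  expect_identical(a, b)
  c_ <- simulate_inputs(6)
  expect_false(identical(a$pollen_stations$value, c_$pollen_stations$value))
})

test_that("noise-free stations read the truth surface exactly", {
  pol <- gen_pollen_surface(synthetic_config(2, station_noise_sdlog = 1e-12))
  cc <- cell_centres(pol$surface$spec)
  truth_at <- mapply(function(x, y) {
    i <- which(abs(as.vector(cc$x) - x) < 1e-6 & abs(as.vector(cc$y) - y) < 1e-6)
    as.vector(pol$surface$values)[i]
  }, pol$stations$x, pol$stations$y)
  expect_equal(pol$stations$value, unname(truth_at), tolerance = 1e-9)
})

test_that("IDW reconstruction from stations correlates with the truth surface", {
  cfg <- synthetic_config(3, n_stations = 100)
  pol <- gen_pollen_surface(cfg)
  rec <- interpolate_idw(pol$stations, cfg$spec)
  expect_gt(cor(as.vector(rec$values), as.vector(pol$surface$values)), 0.8)
})

test_that("sensitisation studies are binomially consistent with their truth field", {
  cfg <- synthetic_config(4, n_tested_range = c(5e4, 5e4))
  st <- gen_sensitisation_studies(cfg)
  cc <- cell_centres(cfg$spec)
  truth <- mapply(function(x, y) {
    i <- which(abs(as.vector(cc$x) - x) < 1e-6 & abs(as.vector(cc$y) - y) < 1e-6)
    as.vector(st$truth_overall$values)[i]
  }, st$overall$x, st$overall$y)
  # with 50k tested per study the rate estimates hug the truth
  expect_lt(max(abs(st$overall$rate - truth)), 0.02)
  expect_true(all(st$overall$rate >= 0 & st$overall$rate <= 1))
  # product-map recovery at defaults
  cfg2 <- synthetic_config(4)
  st2 <- gen_sensitisation_studies(cfg2)
  rec <- grid_sensitisation(st2$overall, st2$conditional, cfg2$spec)
  truth_prod <- st2$truth_overall$values * st2$truth_conditional$values
  rmse <- sqrt(mean((rec$values - truth_prod)^2))
  expect_lt(rmse, 0.05)
})

test_that("community panel honours the invariants and recovers the elasticity", {
  g <- gen_community_health(synthetic_config(5))
  rec <- g$records
  expect_equal(nrow(rec), 313 * 9)
  expect_true(all(rec$patients >= 0))
  expect_true(all(rec$patients <= rec$population))
  cm <- average_by_community(rec, 2007:2015)
  fit <- fit_loglog_origin(cm$mean_pollen, cm$mean_patients)
  expect_lt(abs(fit$beta - g$truth$beta), 3 * fit$se_beta)

  # sigma -> 0, beta = 1: exact proportionality up to integer rounding
  g0 <- gen_community_health(synthetic_config(5, noise_sigma_log = 1e-9,
                                              true_elasticity = 1))
  r0 <- g0$records
  expected <- 10 * r0$pollen_integral * r0$population / 1e5
  expect_lt(max(abs(r0$patients - expected)), 0.5 + 1e-6)
})

test_that("temperature generator: altitude ordering and degenerate flatness", {
  cfg <- synthetic_config(6)
  ser <- gen_daily_temps(cfg)
  means <- vapply(ser, function(s) mean((s$tmin + s$tmax) / 2), numeric(1))
  expect_true(all(diff(means[order(c(130, 250, 480, 700, 1230))]) < 0))
  expect_true(all(vapply(ser, function(s) all(s$tmin <= s$tmax), logical(1))))

  flat <- gen_daily_temps(synthetic_config(6, temp_amplitude = 0,
                                           temp_daily_noise_sd = 0))
  s1 <- flat[[1]]
  expect_lt(diff(range(s1$tmin)), 1e-9)
})

test_that("cohort ladder round-trips the per-generation GDD truth", {
  cfg <- synthetic_config(7)
  ser <- gen_daily_temps(cfg)
  cohorts <- gen_cohorts(cfg, ser)
  expect_gt(nrow(cohorts), 3)
  est <- estimate_generation_gdd(cohorts, ser,
                                 voltinism_params(cfg$base_temp,
                                                  cfg$gdd_per_generation))
  expect_lt(abs(est$mean_gdd - 288.7) / 288.7, 0.02)
})

test_that("plot generator respects its design and degenerate settings", {
  pd <- gen_plot_data(synthetic_config(8))
  expect_equal(sort(unique(pd$plots$site)), c("site1", "site2", "site3"))
  expect_false("beetle_excluded" %in%
                 pd$plots$treatment[pd$plots$site == "site1"])
  expect_equal(sum(pd$plots$site == "site2"), 28)

  sure <- gen_plot_data(synthetic_config(8, p_control = 1, p_excluded = 1,
                                         site_sd_logit = 0))
  expect_true(all(sure$plots$density > 0))
})

test_that("pre/post pollen series honour their target means and reduction shape", {
  cfg <- synthetic_config(9, pollen_series_noise_sdlog = 0.001)
  pp <- gen_prepost_pollen(cfg)
  drop <- prepost_mean_drop(pp$pre, pp$post)
  expect_equal(drop$pre_mean, 46.2, tolerance = 0.01)
  expect_equal(drop$post_mean, 7.5, tolerance = 0.01)
  expect_equal(drop$reduction, 1 - 7.5 / 46.2, tolerance = 1e-3)

  curve <- empirical_reduction_curve(pp$pre, pp$post)
  n <- nrow(curve)
  # strongest suppression early, levelling out at the high cumulative range
  expect_gt(mean(curve$reduction[1:5]), mean(curve$reduction[(n - 4):n]))
  expect_lt(abs(curve$reduction[n] - 0.837), 0.02)
})
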