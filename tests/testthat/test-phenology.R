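const_series <- function(n_days, tmean, diurnal = 0,
                         start = as.Date("2016-06-01")) {
  data.frame(date = start + 0:(n_days - 1),
             tmin = tmean - diurnal / 2, tmax = tmean + diurnal / 2)
}

test_that("GDD accumulation: threshold, exact arithmetic, loop oracle", {
  p <- voltinism_params()
  expect_equal(gdd_accumulate(const_series(15, 13.3), p), 0)
  expect_equal(gdd_accumulate(const_series(10, 23.3), p), 100)

  set.seed(61)
  doy <- 1:30
  tm <- 15 + 8 * sin(2 * pi * doy / 30) + rnorm(30, 0, 2)
  ser <- data.frame(date = as.Date("2016-06-01") + doy - 1,
                    tmin = tm - 4, tmax = tm + 4)
  loop <- 0
  for (i in 1:30) loop <- loop + max(0, (ser$tmin[i] + ser$tmax[i]) / 2 - 13.3)
  expect_equal(gdd_accumulate(ser, p), loop)

  expect_error(gdd_accumulate(ser, p, from = as.Date("2016-05-01")),
               "outside")
})

test_that("GDD is monotone in temperature and additive over windows", {
  p <- voltinism_params()
  ser <- const_series(20, 18)
  warm <- ser; warm$tmax <- warm$tmax + 2
  expect_gte(gdd_accumulate(warm, p), gdd_accumulate(ser, p))
  whole <- gdd_accumulate(ser, p)
  first <- gdd_accumulate(ser, p, to = ser$date[10])
  second <- gdd_accumulate(ser, p, from = ser$date[11])
  expect_equal(first + second, whole)
})

test_that("generation count floors at the per-generation requirement", {
  p <- voltinism_params(13.3, 288.7)
  expect_identical(generations(288.6, p), 0L)
  expect_identical(generations(288.7, p), 1L)
  expect_identical(generations(866.1, p), 3L)

  set.seed(62)
  g <- runif(50, 0, 3000)
  by_subtraction <- vapply(g, function(v) {
    k <- 0L
    while (v >= p$gdd_per_generation - 1e-9) { v <- v - p$gdd_per_generation; k <- k + 1L }
    k
  }, integer(1))
  expect_identical(generations(g, p), by_subtraction)
  expect_true(all(generations(g, p) * p$gdd_per_generation <= g + 1e-9))
})

test_that("cohort GDD estimation reproduces a constructed exact case", {
  # 20 days at a constant daily excess of 288.7/20 degree-days
  p <- voltinism_params(13.3, 288.7)
  ser <- const_series(25, 13.3 + 288.7 / 20)
  cohorts <- data.frame(site = "s1",
                        oviposition_date = ser$date[1],
                        adult_emergence_date = ser$date[20])
  est <- estimate_generation_gdd(cohorts, list(s1 = ser), p)
  expect_equal(est$mean_gdd, 288.7)

  two <- rbind(cohorts, cohorts)
  expect_equal(estimate_generation_gdd(two, list(s1 = ser), p)$mean_gdd, 288.7)

  expect_error(estimate_generation_gdd(
    data.frame(site = "nowhere", oviposition_date = ser$date[1],
               adult_emergence_date = ser$date[5]),
    list(s1 = ser), p), "nowhere")
})

test_that("pre/post mean drop and its error path", {
  pre <- data.frame(station = "a", date = as.Date("2008-08-01") + 0:9,
                    concentration = 46.2)
  same <- prepost_mean_drop(pre, pre)
  expect_equal(same$reduction, 0)

  post0 <- pre; post0$concentration <- 0
  expect_equal(prepost_mean_drop(pre, post0)$reduction, 1)

  post <- pre; post$concentration <- 7.5
  drop <- prepost_mean_drop(pre, post)
  expect_equal(drop$reduction, 1 - 7.5 / 46.2, tolerance = 1e-12)

  expect_error(prepost_mean_drop(post0, pre), "zero")
})

test_that("empirical reduction curve handles flat-ratio cases", {
  pre <- data.frame(station = rep(c("a", "b"), each = 10),
                    date = rep(as.Date("2008-08-01") + 0:9, 2),
                    concentration = rep(10 * (1:10), 2))
  half <- pre; half$concentration <- half$concentration / 2
  cv <- empirical_reduction_curve(pre, half)
  expect_true(all(abs(cv$reduction - 0.5) < 1e-12))
  expect_true(all(diff(cv$level) > 0))

  zero <- pre; zero$concentration <- 0
  expect_true(all(empirical_reduction_curve(pre, zero)$reduction == 1))
})

test_that("reduction grid applies the generation policy inside the masks", {
  pol <- reduction_policy(0.86, 0.30)
  ones <- toy_grid(matrix(1, 4, 4))
  g5 <- toy_grid(matrix(5, 4, 4))
  expect_equal(reduction_grid(g5, pol, ones, ones)$values, matrix(0.86, 4, 4))

  g2 <- toy_grid(matrix(2, 4, 4))
  half_mask <- toy_grid(matrix(rep(c(1, 0), each = 8), 4, 4))
  r2 <- reduction_grid(g2, pol, half_mask, ones)
  expect_equal(r2$values, matrix(rep(c(0.30, 0), each = 8), 4, 4))

  gen <- toy_grid(matrix(c(0, 1, 2, 3, 4, 0, 1, 2, 3, 4, 0, 1, 2, 3, 4, 0), 4, 4))
  r <- reduction_grid(gen, pol, ones, ones)
  want <- matrix(c(0, .3, .3, .86, .86, 0, .3, .3, .86, .86, 0, .3, .3, .86, .86, 0), 4, 4)
  expect_equal(r$values, want)
  expect_true(all(r$values %in% c(0, 0.30, 0.86)))
  # monotone in generations
  ord <- order(as.vector(gen$values))
  expect_true(all(diff(as.vector(r$values)[ord]) >= 0))
})
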