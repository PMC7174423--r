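test_that("allometry fit recovers exact and noisy linear relations", {
  x <- seq(1, 4, length.out = 10)
  exact <- fit_allometry(data.frame(log_volume = x, log_raceme = 2 * x + 1))
  expect_equal(exact$alpha, 1, tolerance = 1e-10)
  expect_equal(exact$beta, 2, tolerance = 1e-10)

  flat <- fit_allometry(data.frame(log_volume = x, log_raceme = 7))
  expect_equal(flat$beta, 0, tolerance = 1e-12)
  expect_equal(flat$alpha, 7, tolerance = 1e-12)

  set.seed(71)
  v <- rnorm(21, 3, 0.8)
  y <- -2 + 1.3 * v + rnorm(21, 0, 0.3)
  f <- fit_allometry(data.frame(log_volume = v, log_raceme = y))
  # normal equations evaluated directly
  b_hat <- sum((v - mean(v)) * (y - mean(y))) / sum((v - mean(v))^2)
  a_hat <- mean(y) - b_hat * mean(v)
  expect_equal(f$beta, b_hat, tolerance = 1e-12)
  expect_equal(f$alpha, a_hat, tolerance = 1e-12)

  expect_error(fit_allometry(data.frame(log_volume = rep(2, 5),
                                        log_raceme = 1:5)), "distinct")
})

test_that("plot raceme density follows r = n * m * exp(v*beta + alpha) / area", {
  expect_equal(plot_raceme_density(0, 0.5, 2, 1, 1), 0)
  expect_equal(plot_raceme_density(10, 0.5, 0, 0, 1), 20)  # r = 5 over 0.25 m2
  # paper-scale synthetic plot, hand-evaluated
  r <- 12 * 0.75 * exp(3.1 * 1.3 + (-2))
  expect_equal(plot_raceme_density(12, 0.75, 3.1, -2, 1.3), r / 0.25)
  # linear in n and m, log-linear in v
  expect_equal(plot_raceme_density(24, 0.75, 3.1, -2, 1.3),
               2 * plot_raceme_density(12, 0.75, 3.1, -2, 1.3))
  expect_equal(plot_raceme_density(12, 0.75, 4.1, -2, 1.3),
               exp(1.3) * plot_raceme_density(12, 0.75, 3.1, -2, 1.3))
  expect_error(plot_raceme_density(5, 1.2, 1, 0, 1), "frac_matured")
})

test_that("plot-table densities use site-treatment mean volume when unmeasured", {
  allom <- data.frame(site = "s", treatment = "control", year = 2015,
                      alpha = 0, beta = 1, n = 21, borrowed_from_year = 2015)
  plots <- data.frame(plot = c("p1", "p2", "p3"), site = "s",
                      treatment = "control", year = 2015,
                      n_plants = c(4, 4, 0), frac_matured = c(0.5, 0.5, 0),
                      mean_log_volume = c(2, NA, NA))
  out <- estimate_plot_densities(plots, allom)
  expect_equal(out$density[1], 4 * 0.5 * exp(2) / 0.25)
  expect_equal(out$density[2], out$density[1])  # borrowed v = mean(2)
  expect_equal(out$density[3], 0)               # empty plot needs no volume
})

test_that("allometry table borrows an earlier year for sparse groups", {
  set.seed(72)
  v <- rnorm(21, 3, 0.8)
  s15 <- data.frame(site = "m", treatment = "control", year = 2015,
                    log_volume = v, log_raceme = -2 + 1.3 * v + rnorm(21, 0, .3))
  s16 <- data.frame(site = "m", treatment = "control", year = 2016,
                    log_volume = rnorm(2, 3, 1),
                    log_raceme = rnorm(2, 2, 1))
  tab <- fit_allometry_table(rbind(s15, s16), min_n = 5)
  r16 <- tab[tab$year == 2016, ]
  r15 <- tab[tab$year == 2015, ]
  expect_equal(r16$borrowed_from_year, 2015)
  expect_equal(r16$alpha, r15$alpha)
  expect_equal(r16$beta, r15$beta)
})

test_that("Laplace GLMM with variance fixed at zero equals a plain GLM", {
  set.seed(73)
  d <- gen_plot_data(synthetic_config(3))$plots
  y <- as.numeric(d$density > 0)
  X <- cbind(1, as.numeric(d$treatment == "beetle_excluded"))
  mine <- fit_glmm_laplace(y, X, d$site, "binomial", sigma = 0)
  ref <- glm(y ~ X - 1, family = binomial())
  expect_lt(max(abs(mine$coef - coef(ref))), 1e-6)
  expect_equal(mine$loglik, as.numeric(logLik(ref)), tolerance = 1e-8)

  pos <- d$density > 0
  yp <- floor(d$density[pos] + 0.5)
  Xp <- X[pos, , drop = FALSE]
  mine_p <- fit_glmm_laplace(yp, Xp, d$site[pos], "poisson", sigma = 0)
  ref_p <- glm(yp ~ Xp - 1, family = poisson())
  expect_lt(max(abs(mine_p$coef - coef(ref_p))), 1e-6)
})

test_that("Laplace GLMM agrees with the independent lme4 fit", {
  library(lme4)
  d <- gen_plot_data(synthetic_config(7))$plots
  d$produce <- as.numeric(d$density > 0)
  d$tr <- as.numeric(d$treatment == "beetle_excluded")
  X <- cbind(1, d$tr)
  mine <- fit_glmm_laplace(d$produce, X, d$site, "binomial")
  ref <- suppressMessages(glmer(produce ~ tr + (1 | site), data = d,
                                family = binomial))
  expect_lt(max(abs(mine$coef - fixef(ref))), 1e-3)
  expect_equal(mine$loglik, as.numeric(logLik(ref)), tolerance = 1e-5)

  pos <- d[d$density > 0, ]
  pos$y <- floor(pos$density + 0.5)
  mine_p <- fit_glmm_laplace(pos$y, cbind(1, pos$tr), pos$site, "poisson")
  ref_p <- suppressMessages(glmer(y ~ tr + (1 | site), data = pos,
                                  family = poisson))
  expect_lt(max(abs(mine_p$coef - fixef(ref_p))), 1e-3)
  expect_equal(mine_p$sigma, sqrt(unname(unlist(VarCorr(ref_p)))),
               tolerance = 1e-3)
})

test_that("hurdle fit handles degenerate designs: all produce, single site", {
  set.seed(74)
  allpos <- data.frame(site = rep(c("a", "b"), each = 6),
                       treatment = rep(c("control", "beetle_excluded"), 6),
                       density = rpois(12, 300) + 1)
  f <- fit_hurdle(allpos)
  expect_gt(f$p_produce["control"], 0.99)
  expect_gt(f$p_produce["beetle_excluded"], 0.99)
  expect_true(f$boundary["binomial"])
  expect_true(is.na(f$lrt_p["binomial"]))

  one_site <- data.frame(site = "solo",
                         treatment = rep(c("control", "beetle_excluded"), each = 10),
                         density = c(rbinom(10, 1, 0.3) * rpois(10, 200),
                                     rbinom(10, 1, 0.8) * rpois(10, 800)))
  f1 <- fit_hurdle(one_site)
  # with one group the variance collapses and the fit matches a plain GLM
  y <- as.numeric(one_site$density > 0)
  X <- cbind(1, as.numeric(one_site$treatment == "beetle_excluded"))
  ref <- glm(y ~ X - 1, family = binomial())
  expect_lt(max(abs(f1$parts$binomial$coef - coef(ref))), 1e-3)
})

test_that("expected density and production reduction arithmetic", {
  fake <- structure(list(
    p_produce = c(control = 0.26, beetle_excluded = 0.84),
    mean_positive_density = c(control = 260, beetle_excluded = 905)),
    class = "hurdle_fit")
  expect_equal(expected_density(fake, "beetle_excluded"), 0.84 * 905)
  expect_equal(expected_density(fake, "control"), 0.26 * 260)

  red <- percent_production_reduction(fake)
  expect_equal(red$per_year, 100 * (1 - 67.6 / 760.2), tolerance = 1e-12)

  equal <- c(control = 500, beetle_excluded = 500)
  expect_equal(percent_production_reduction(equal)$per_year, 0)
  only_excl <- c(control = 0, beetle_excluded = 700)
  expect_equal(percent_production_reduction(only_excl)$per_year, 100)
  # multi-year mean: a 2016-like year of zero control production joins as 100%
  both <- percent_production_reduction(fake, only_excl)
  expect_equal(both$mean, mean(c(100 * (1 - 67.6 / 760.2), 100)))
})
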