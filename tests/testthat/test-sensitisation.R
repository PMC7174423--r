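make_studies <- function(n, rate, kind, lo = 0, hi = 30) {
  data.frame(id = paste0(substr(kind, 1, 2), seq_len(n)),
             x = seq(lo, hi, length.out = n),
             y = seq(hi, lo, length.out = n),
             rate = rate, n_tested = 100, kind = kind,
             stringsAsFactors = FALSE)
}

test_that("sensitisation grid is the product of the two IDW rate layers", {
  spec <- toy_spec(4, 4)
  ov <- make_studies(3, 0.30, "overall")
  cd <- make_studies(3, 0.50, "ragweed_given_sensitised")
  g <- grid_sensitisation(ov, cd, spec)
  expect_equal(g$values, matrix(0.15, 4, 4), tolerance = 1e-12)

  cd0 <- make_studies(3, 0, "ragweed_given_sensitised")
  expect_true(all(grid_sensitisation(ov, cd0, spec)$values == 0))

  # composition of brute-force oracles, heterogeneous rates
  set.seed(31)
  ov2 <- make_studies(3, runif(3, 0.1, 0.5), "overall")
  cd2 <- make_studies(3, runif(3, 0.2, 0.9), "ragweed_given_sensitised")
  ov2$x <- runif(3, 0, 40); ov2$y <- runif(3, 0, 40)
  cd2$x <- runif(3, 0, 40); cd2$y <- runif(3, 0, 40)
  got <- grid_sensitisation(ov2, cd2, spec, k = 3)
  want <- oracle_idw(data.frame(x = ov2$x, y = ov2$y, value = ov2$rate), spec) *
    oracle_idw(data.frame(x = cd2$x, y = cd2$y, value = cd2$rate), spec)
  expect_equal(got$values, want, tolerance = 1e-10)
  expect_true(all(got$values >= 0 & got$values <= 1))

  expect_error(grid_sensitisation(rbind(ov, cd[, names(ov)]), cd, spec), "mixed")
})

test_that("clinical patient grid multiplies rate, population and relevance", {
  sens <- toy_grid(matrix(1, 3, 3))
  pop <- toy_grid(matrix(10 * (1:9), 3, 3))
  country <- toy_grid(matrix(c(1, 1, 1, 1, 2, 2, 2, 2, 2), 3, 3))
  ident <- clinical_patients_grid(sens, pop, country, c(`1` = 1, `2` = 1))
  expect_equal(ident$values, pop$values)

  zeroed <- clinical_patients_grid(sens, pop, country, c(`1` = 0, `2` = 1))
  expect_true(all(zeroed$values[country$values == 1] == 0))

  # two-country toy against a hand-computed spreadsheet
  sens2 <- toy_grid(matrix(0.5, 3, 3))
  got <- clinical_patients_grid(sens2, pop, country, c(`1` = 0.6, `2` = 0.9))
  want <- 0.5 * pop$values * ifelse(country$values == 1, 0.6, 0.9)
  expect_equal(got$values, want)
  expect_true(all(got$values <= pop$values))

  expect_error(clinical_patients_grid(sens, pop, country, c(`1` = 1)),
               "missing.*2")
})

test_that("exposure mask uses a strict threshold, zeroes (not drops) cells, idempotent", {
  pat <- toy_grid(matrix(5, 2, 2))
  below <- toy_grid(matrix(9.99, 2, 2))
  at <- toy_grid(matrix(10, 2, 2))
  expect_true(all(apply_exposure_mask(pat, below, 10)$values == 0))
  expect_equal(apply_exposure_mask(pat, at, 10)$values, pat$values)

  mixed <- toy_grid(matrix(c(0, 5, 10, 20), 2, 2))
  m1 <- apply_exposure_mask(pat, mixed, 10)
  expect_equal(m1$values, matrix(c(0, 0, 5, 5), 2, 2))
  expect_false(anyNA(m1$values))
  expect_equal(apply_exposure_mask(m1, mixed, 10)$values, m1$values)
})

test_that("patient counting sums per country and conserves the grand total", {
  country <- toy_grid(matrix(c(1, 1, 2, 2), 2, 2))
  zero <- count_patients(toy_grid(matrix(0, 2, 2)), country)
  expect_true(all(zero$by_country == 0))

  single <- toy_grid(matrix(c(0, 1234.5, 0, 0), 2, 2))
  got <- count_patients(single, country)
  expect_equal(unname(got$by_country["1"]), 1234.5)
  expect_equal(got$total, sum(got$by_country))

  set.seed(32)
  vals <- matrix(runif(4, 0, 100), 2, 2)
  g <- count_patients(toy_grid(vals), country)
  expect_equal(unname(g$by_country["1"]), sum(vals[country$values == 1]))
  expect_equal(g$total, sum(vals))

  # refining one country into two leaves the grand total unchanged
  refined <- toy_grid(matrix(c(1, 3, 2, 2), 2, 2))
  expect_equal(count_patients(toy_grid(vals), refined)$total, g$total)
})

test_that("raising a study rate never lowers any cell's sensitisation", {
  spec <- toy_spec(5, 5)
  set.seed(33)
  ov <- make_studies(4, runif(4, 0.2, 0.4), "overall")
  cd <- make_studies(4, runif(4, 0.3, 0.6), "ragweed_given_sensitised")
  base <- grid_sensitisation(ov, cd, spec, k = 4)
  for (i in seq_len(nrow(ov))) {
    up <- ov; up$rate[i] <- up$rate[i] + 0.1
    bumped <- grid_sensitisation(up, cd, spec, k = 4)
    expect_true(all(bumped$values >= base$values - 1e-12))
  }
})
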