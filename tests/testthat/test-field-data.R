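test_that("theta conversion reproduces the published per-trial inputs", {
  cfg <- trial_config()
  hi <- total_inputs(production_series(2000, 4.8, 2.3), cfg)
  expect_equal(round(hi$input, 1), 3.0)            # high-fertilizer trial
  rf <- total_inputs(production_series(2000, 3.8, 2.1), cfg)
  expect_equal(round(rf$input, 1), 2.6)            # residual-fertilizer trial
  expect_equal(total_inputs(production_series(2000, 0, 0), cfg)$input, 0)

  # linear in both production columns
  a <- total_inputs(production_series(2000, 2, 1), cfg)$input
  b <- total_inputs(production_series(2000, 4, 2), cfg)$input
  expect_equal(b, 2 * a)

  prod <- production_series(2000:2002, c(2, NA, 4), 1)
  expect_error(total_inputs(prod, cfg), "2001")
})

test_that("gap filling substitutes per-column means and is idempotent", {
  prod <- production_series(2000:2002, c(2, NA, 4), c(NA, 3, 5))
  filled <- gap_fill(prod)
  expect_equal(filled$aboveground, c(2, 3, 4))
  expect_equal(filled$belowground, c(4, 3, 5))
  expect_identical(gap_fill(filled), filled)

  one <- gap_fill(production_series(2000:2003, c(5, NA, NA, NA), 1))
  expect_equal(one$aboveground, rep(5, 4))

  expect_error(gap_fill(production_series(2000:2001, NA, 1)),
               "no observed values")
})

test_that("stock arithmetic from %C, bulk density and depth", {
  expect_equal(stock_from_carbon_content(5, 1.14, 2), 11.4)   # scraping loss
  expect_equal(round(stock_from_carbon_content(5, 1.14, 2)), 11)
  expect_equal(stock_from_carbon_content(0, 1.14, 7.5), 0)
  expect_equal(stock_from_carbon_content(3.5, 1.14, 7.5), 29.925)
  # homogeneous of degree 1 in each argument
  expect_equal(stock_from_carbon_content(7, 1.14, 2),
               1.4 * stock_from_carbon_content(5, 1.14, 2))
  expect_equal(stock_from_carbon_content(5, 2.28, 2),
               2 * stock_from_carbon_content(5, 1.14, 2))
})

test_that("polynomial initial-stock regression", {
  obs <- observation_series(2000:2010, 20 + 0.5 * (0:10))
  expect_equal(fit_initial_stock(obs, 1, 2000), 20)
  expect_equal(fit_initial_stock(obs, 1, 1995), 17.5)

  const <- observation_series(2000:2006, rep(31, 7))
  expect_equal(fit_initial_stock(const, 2, 2003), 31)

  expect_error(fit_initial_stock(observation_series(2000:2002, 1:3), 2, 2000),
               "at least")

  # quadratic truth + noise: recovered within 3x the fit standard error
  set.seed(21)
  yrs <- 1971:2010
  truth <- function(y) 25 + 0.3 * (y - 1971) - 0.004 * (y - 1971)^2
  obs2 <- observation_series(yrs, truth(yrs) + rnorm(40, 0, 0.5))
  est <- fit_initial_stock(obs2, 2, 1971)
  ref <- lm(stock ~ poly(year, 2, raw = TRUE), data = obs2)   # oracle
  se <- predict(ref, newdata = data.frame(year = 1971), se.fit = TRUE)$se.fit
  expect_lt(abs(est - truth(1971)), 3 * se)
})

test_that("capture efficiency matches every published trial value", {
  tab <- winchmore_trials()
  expect_equal(round(capture_efficiency(tab$soc_increase, tab$inputs_mean), 1),
               tab$capture_efficiency)
  expect_equal(capture_efficiency(0, 2), 0)
  expect_error(capture_efficiency(0.2, 0), "positive")
})

test_that("per-mille accumulation metric", {
  expect_equal(accumulation_permille(0.2, 25), 8)
  expect_equal(accumulation_permille(0, 25), 0)
  expect_equal(accumulation_permille(0.031, 31), 1)
  expect_error(accumulation_permille(0.2, 0), "positive")
})

test_that("production and observation CSV readers", {
  pp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("year,aboveground,belowground", "1960,2.5,", "1961,,2.0"),
             pp)
  prod <- read_production_table(pp)
  expect_true(is.na(prod$belowground[1]) && is.na(prod$aboveground[2]))

  op <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("year,stock,delta14c", "1960,30.5,-35", "1961,30.9,"), op)
  obs <- read_observation_table(op)
  expect_equal(obs$stock, c(30.5, 30.9))
  expect_equal(obs$delta14c, c(-35, NA))
  expect_equal(obs$stock_sd, c(1.5, 1.5))    # defaults applied
  expect_equal(obs$delta_sd, c(8.9, 8.9))
})
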