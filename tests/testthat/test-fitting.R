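# shared small synthetic dataset for the fitting tests
make_fit_case <- function(seed = 42, noise = TRUE) {
  atm <- synth_atmosphere()
  scen <- truth_scenario(seed = seed)
  obs <- synth_observations(scen, atm, noise = noise)
  win <- fit_window(scen$window[1], scen$window[2], obs, attr(obs, "inputs"),
                    initial_delta_mode = "window2")
  list(atm = atm, scen = scen, obs = obs, win = win)
}

test_that("windows require the joint stock + radiocarbon constraint", {
  inputs <- input_series(1985:2010, 3)
  obs_nod <- observation_series(1985:2010, seq(30, 37, length.out = 26))
  expect_error(fit_window(1985, 2010, obs_nod, inputs), "radiocarbon")
  obs_end <- obs_nod
  obs_end$delta14c[1:3] <- 100
  expect_error(fit_window(1985, 2010, obs_end, inputs), "near both")
  expect_error(fit_window(2010, 1985, obs_nod, inputs), "precede")
})

test_that("residuals vanish on self-consistent data and scale with sd", {
  fc <- make_fit_case(noise = FALSE)
  win <- fc$win
  win$initial_stock <- fc$scen$initial_stock
  r <- window_residuals(fc$scen$params, win, fc$atm)
  expect_lt(max(abs(r)), 1e-3)

  fc2 <- make_fit_case()
  r1 <- window_residuals(fc2$scen$params, fc2$win, fc2$atm)
  win2 <- fc2$win
  win2$observations$stock_sd <- 2 * win2$observations$stock_sd
  win2$observations$delta_sd <- 2 * win2$observations$delta_sd
  r2 <- window_residuals(fc2$scen$params, win2, fc2$atm)
  expect_equal(r2, r1 / 2)

  # perturbing k1 away from truth increases the sum of squares
  perturbed <- fc2$scen$params
  perturbed$k1 <- perturbed$k1 * 1.5
  expect_gt(window_cost(perturbed, fc2$win, fc2$atm),
            window_cost(fc2$scen$params, fc2$win, fc2$atm))

  # cost is invariant to observation order
  win3 <- fc2$win
  win3$observations <- win3$observations[rev(seq_len(nrow(win3$observations))), ]
  expect_equal(window_cost(fc2$scen$params, win3, fc2$atm),
               window_cost(fc2$scen$params, fc2$win, fc2$atm))

  expect_equal(window_cost(fc2$scen$params, fc2$win, fc2$atm), sum(r1^2))
})

test_that("MCMC respects bounds, is reproducible, and recovers truth", {
  fc <- make_fit_case(seed = 7)
  post <- run_mcmc(fc$win, fc$atm, n_iter = 4000, seed = 5)
  b <- default_parameter_bounds()
  draws <- post$draws[, names(b$lower)]
  expect_true(all(t(draws) >= b$lower & t(draws) <= b$upper))
  expect_true(all(draws$k1 > draws$k2))
  expect_gt(post$acceptance_rate, 0.01)

  post2 <- run_mcmc(fc$win, fc$atm, n_iter = 4000, seed = 5)
  expect_identical(post$draws, post2$draws)

  truth <- c(k1 = 0.15, k2 = 0.008, a21 = 0.10, slowProp = 0.55)
  s <- post$summary
  expect_true(all(abs(s$mean - truth[s$parameter]) <= 2 * s$sd))

  expect_error(run_mcmc(fc$win, fc$atm, init = c(k1 = 2, k2 = 0.01,
                                                 a21 = 0.5, slowProp = 0.5)),
               "bounds")
})

test_that("iterative initial fast-pool delta estimation converges", {
  atm <- synth_atmosphere()
  scen <- truth_scenario(initial_stock = 32, window = c(1958, 1992),
                         seed = 5)
  obs <- synth_observations(scen, atm, initial_delta_mode = "window1")
  win <- fit_window(1958, 1992, obs, attr(obs, "inputs"),
                    initial_delta_mode = "window1")

  first_pass <- estimate_initial_fast_delta(win, atm, tol = Inf,
                                            n_iter = 1000, seed = 3)
  expect_equal(attr(first_pass, "iterations"), 1L)

  est <- estimate_initial_fast_delta(win, atm, tol = 0.5, n_iter = 1500,
                                     seed = 3)
  truth_delta <- delta_from_ratio(
    one_pool_equilibrium_ratio(scen$params$k1, atm, 1958))
  expect_lt(abs(as.numeric(est) - truth_delta), 2)

  expect_error(estimate_initial_fast_delta(fit_window(
    1985, 2010, obs <- synth_observations(truth_scenario(seed = 2), atm),
    attr(obs, "inputs"), initial_delta_mode = "window2"), atm),
    "window-1")
})

test_that("constant atmosphere makes the iteration settle immediately", {
  atm <- const_atm(0)
  scen <- truth_scenario(initial_stock = 32, window = c(1958, 1992),
                         seed = 9)
  obs <- synth_observations(scen, atm, initial_delta_mode = "window1")
  win <- fit_window(1958, 1992, obs, attr(obs, "inputs"),
                    initial_delta_mode = "window1")
  est <- estimate_initial_fast_delta(win, atm, tol = 0.5, n_iter = 800,
                                     seed = 2)
  expect_lte(attr(est, "iterations"), 2L)
  k1_hat <- attr(est, "k1")
  expect_equal(ratio_from_delta(as.numeric(est)),
               k1_hat / (k1_hat + LAMBDA_14C), tolerance = 1e-5)
})

test_that("bootstrap intervals are percentile-based and nested", {
  fc <- make_fit_case(seed = 3)
  post <- run_mcmc(fc$win, fc$atm, n_iter = 1500, seed = 4)

  const_ci <- bootstrap_summaries(post, function(p) 1.5, n_boot = 200,
                                  seed = 1)
  expect_equal(const_ci$lower, const_ci$upper)

  wide <- bootstrap_summaries(post, function(p) tt_quantile(p, 0.5),
                              n_boot = 400, level = 0.99, seed = 1)
  narrow <- bootstrap_summaries(post, function(p) tt_quantile(p, 0.5),
                                n_boot = 400, level = 0.5, seed = 1)
  expect_gte(narrow$lower, wide$lower)
  expect_lte(narrow$upper, wide$upper)

  # a synthetic normal posterior: the percentile CI matches the
  # analytic quantiles within Monte-Carlo error
  fake <- post
  set.seed(8)
  fake$draws <- data.frame(k1 = rnorm(5000, 0.15, 0.01),
                           k2 = rep(0.008, 5000), a21 = rep(0.1, 5000),
                           slowProp = rep(0.5, 5000), cost = 0)
  ci <- bootstrap_summaries(fake, function(p) p$k1, n_boot = 2000,
                            level = 0.99, seed = 2)
  # Monte-Carlo error of an extreme-quantile estimate from 2000 draws
  mc_se <- sqrt(0.005 * 0.995 / 2000) / dnorm(qnorm(0.995)) * 0.01
  expect_lt(abs(ci$lower - qnorm(0.005, 0.15, 0.01)), 4 * mc_se)
  expect_lt(abs(ci$upper - qnorm(0.995, 0.15, 0.01)), 4 * mc_se)
})

test_that("least-squares AIC arithmetic and guards", {
  expect_gt(aic_ls(10, 30, 6), aic_ls(10, 30, 4))
  expect_equal(aic_ls(30, 30, 4), 8)
  expect_error(aic_ls(0, 30, 4), "positive")
  expect_error(aic_ls(10, 4, 4), "exceed")
})

test_that("goodness-of-fit summary reports native-unit RMSEs", {
  fc <- make_fit_case(seed = 12)
  post <- run_mcmc(fc$win, fc$atm, n_iter = 1500, seed = 2)
  fr <- evaluate_fit(post, fc$win, fc$atm)
  expect_gt(fr$rmse_stock, 0)
  expect_lt(fr$rmse_stock, 3)      # ~ observation noise, Mg C ha^-1
  expect_gt(fr$rmse_delta, 0)
  expect_lt(fr$rmse_delta, 20)     # per mil
  expect_true(is.finite(fr$aic))
})

test_that("splitting a drifting record into windows improves the fit", {
  # truth drifts: faster cycling early, slower late (the qualitative
  # pattern the two-window design addresses)
  atm <- synth_atmosphere()
  p_early <- pool_params(0.25, 0.014, 0.15, 0.65)
  p_late <- pool_params(0.15, 0.008, 0.08, 0.55)
  inputs <- input_series(1958:2010, 2.8)
  d0 <- initial_pool_deltas(p_early, atm, 1958, "window1")
  st0 <- initial_state(30, p_early, d0[["fast"]], d0[["slow"]], 1958)
  tr1 <- simulate_pools(p_early, inputs, atm, st0, 1985)
  mid <- nrow(tr1)
  stmid <- model_state(1985, c(tr1$C1[mid], tr1$C2[mid]),
                       c(tr1$F1[mid], tr1$F2[mid]))
  tr2 <- simulate_pools(p_late, inputs, atm, stmid, 2010.5)

  years <- 1958:2010
  pick <- function(tr, yrs) {
    idx <- round((yrs + 0.5 - tr$time[1]) * 12) + 1L
    list(stock = tr$total_stock[idx], delta = tr$delta14c_bulk[idx])
  }
  y1 <- years[years < 1985]; y2 <- years[years >= 1985]
  v1 <- pick(tr1, y1); v2 <- pick(tr2, y2)
  set.seed(17)
  dyears <- round(seq(1958, 2010, length.out = 14))
  obs <- observation_series(
    years, c(v1$stock, v2$stock) + rnorm(53, 0, 1),
    ifelse(years %in% dyears, c(v1$delta, v2$delta) + rnorm(53, 0, 5), NA),
    stock_sd = 1, delta_sd = 5)

  fit_rmse <- function(start, end) {
    win <- fit_window(start, end, obs, inputs,
                      initial_delta_mode = if (start < 1980) "window1"
                                           else "window2")
    post <- run_mcmc(win, atm, n_iter = 2500, seed = 6)
    fr <- evaluate_fit(post, win, atm)
    c(stock = fr$rmse_stock, delta = fr$rmse_delta)
  }
  full <- fit_rmse(1958, 2010)
  w1 <- fit_rmse(1958, 1992)
  w2 <- fit_rmse(1985, 2010)
  expect_lt(mean(c(w1["delta"], w2["delta"])), full["delta"])
})
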